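#' Read an expression matrix into a donor profile
#'
#' Reads dense CSV/TSV or sparse Matrix Market (MTX) count matrices.  The
#' on-disk orientation must be declared explicitly -- silent guessing is
#' forbidden.  For MTX the conventional scRNA-seq orientation
#' (genes-as-rows) is the default and companion gene/cell name files are
#' required; for CSV/TSV the default is cells-as-rows with gene names in the
#' header line.
#'
#' @param matrix_path path to the matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param donor_id donor identifier (default: file name).
#' @param genes_path,cells_path for `mtx`: one name per line, matching the
#'   matrix dimensions.
#' @param orientation `"genes_as_rows"` or `"cells_as_rows"`; default
#'   `"genes_as_rows"` for mtx, `"cells_as_rows"` for csv/tsv.
#' @param ... passed to [donor_profile] (e.g. `group_label`).
#' @return a [donor_profile], cells in rows, genes in columns.
#' @export
read_expression_matrix <- function(matrix_path, format = c("csv", "tsv", "mtx"),
                                   donor_id = NULL, genes_path = NULL,
                                   cells_path = NULL, orientation = NULL, ...) {
  format <- match.arg(format)
  if (is.null(donor_id))
    donor_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  if (format == "mtx") {
    if (is.null(orientation)) orientation <- "genes_as_rows"
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx format requires genes_path and cells_path", call. = FALSE)
    m <- as.matrix(Matrix::readMM(matrix_path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (orientation == "cells_as_rows") m <- t(m)
    # now genes in rows
    if (length(genes) != nrow(m))
      stop("gene name file has ", length(genes), " entries but matrix has ",
           nrow(m), " gene rows", call. = FALSE)
    if (length(cells) != ncol(m))
      stop("cell name file has ", length(cells), " entries but matrix has ",
           ncol(m), " cell columns", call. = FALSE)
    expr <- t(m)
    rownames(expr) <- cells
    return(donor_profile(expr, donor_id, feature_names = genes, ...))
  }
  sep <- if (format == "csv") "," else "\t"
  if (is.null(orientation)) orientation <- "cells_as_rows"
  df <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                          row.names = NULL, check.names = FALSE)
  # a leading non-numeric column holds row names
  if (ncol(df) > 1 && !is.numeric(df[[1]])) {
    rn <- as.character(df[[1]]); df <- df[-1]
  } else rn <- NULL
  m <- as.matrix(df)
  if (!is.null(rn)) rownames(m) <- rn
  if (orientation == "genes_as_rows") m <- t(m)
  donor_profile(m, donor_id, ...)
}

#' Inverse hyperbolic sine transform
#'
#' The standard cytometry normalization `asinh(intensity / cofactor)`,
#' applied entrywise with the conventional cofactor 5.
#'
#' @param profile a [donor_profile].
#' @param cofactor positive scaling divisor (default 5).
#' @return the transformed profile; shape and names unchanged.
#' @export
asinh_transform <- function(profile, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("`cofactor` must be a single positive number", call. = FALSE)
  profile$expression <- asinh(profile$expression / cofactor)
  profile
}

#' Quality-control thresholds for scRNA-seq cells
#'
#' Defaults follow common PBMC practice: cells with fewer than 200 or more
#' than 7000 detected genes, more than 70,000 total counts, or more than 10
#' percent mitochondrial counts are removed.  All four inequalities are
#' strict, so boundary cells are retained.
#'
#' @param min_features_per_cell,max_features_per_cell detected-gene bounds.
#' @param max_counts_per_cell total-count ceiling.
#' @param max_mito_percent mitochondrial percentage ceiling, in `[0, 100]`.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_features_per_cell = 200,
                          max_features_per_cell = 7000,
                          max_counts_per_cell = 70000,
                          max_mito_percent = 10) {
  if (min_features_per_cell >= max_features_per_cell)
    stop("min_features_per_cell must be < max_features_per_cell",
         call. = FALSE)
  if (max_mito_percent < 0 || max_mito_percent > 100)
    stop("max_mito_percent must be in [0, 100]", call. = FALSE)
  structure(list(min_features_per_cell = min_features_per_cell,
                 max_features_per_cell = max_features_per_cell,
                 max_counts_per_cell = max_counts_per_cell,
                 max_mito_percent = max_mito_percent),
            class = "qc_thresholds")
}

#' Remove low-quality cells from a raw-count profile
#'
#' A cell is removed when any of the four criteria fires (strict
#' inequalities): detected genes below `min_features_per_cell` or above
#' `max_features_per_cell`, total counts above `max_counts_per_cell`, or
#' mitochondrial percentage above `max_mito_percent`.  Detected genes are
#' genes with count > 0; the mitochondrial percentage is 100 times the count
#' share of genes whose name starts with `mito_gene_prefix`.
#'
#' @param profile a [donor_profile] holding raw (non-negative) counts.
#' @param thresholds a [qc_thresholds] object.
#' @param mito_gene_prefix gene-name prefix marking mitochondrial genes.
#' @return the filtered profile; `metadata$qc_removed` tallies removals per
#'   criterion (a cell may count toward several).
#' @export
qc_filter_cells <- function(profile, thresholds = qc_thresholds(),
                            mito_gene_prefix = "MT-") {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  x <- profile$expression
  if (any(x < 0))
    stop("qc_filter_cells expects raw non-negative counts", call. = FALSE)
  detected <- rowSums(x > 0)
  total <- rowSums(x)
  mito <- startsWith(profile$feature_names, mito_gene_prefix)
  pct_mt <- if (any(mito)) 100 * rowSums(x[, mito, drop = FALSE]) /
                           pmax(total, .Machine$double.eps)
            else rep(0, nrow(x))
  low_feat  <- detected < thresholds$min_features_per_cell
  high_feat <- detected > thresholds$max_features_per_cell
  high_cnt  <- total > thresholds$max_counts_per_cell
  high_mt   <- pct_mt > thresholds$max_mito_percent
  drop <- low_feat | high_feat | high_cnt | high_mt
  tally <- c(low_features = sum(low_feat), high_features = sum(high_feat),
             high_counts = sum(high_cnt), high_mito = sum(high_mt))
  if (all(drop))
    stop("all ", nrow(x), " cells of donor '", profile$donor_id,
         "' removed by QC (dominant criterion: ",
         names(tally)[which.max(tally)], ")", call. = FALSE)
  profile$expression <- x[!drop, , drop = FALSE]
  profile$metadata$qc_removed <- tally
  profile
}

#' Log-normalize a raw-count profile
#'
#' Entry `(c, g)` becomes `ln(1 + count(c,g) / total_count(c) * scale_factor)`
#' -- the convention of the standard single-cell log normalization, with the
#' usual scale factor of 10,000.
#'
#' @param profile a [donor_profile] of raw counts; every cell must have a
#'   positive total.
#' @param scale_factor library-size scaling constant (default 10000).
#' @return the normalized profile.
#' @export
log_normalize <- function(profile, scale_factor = 10000) {
  x <- profile$expression
  total <- rowSums(x)
  if (any(total <= 0))
    stop(sum(total <= 0), " cell(s) with zero total counts; run ",
         "qc_filter_cells() first", call. = FALSE)
  profile$expression <- log1p(x / total * scale_factor)
  profile
}

#' Filter genes by pooled expression across a cohort
#'
#' Keeps genes whose expression summed over every cell of every profile
#' strictly exceeds `threshold`.  A minimum pooled expression makes per-gene
#' distributional comparisons robust and bounds the per-gene scan cost.
#'
#' @param profiles list of [donor_profile]s sharing identical feature names.
#' @param threshold pooled-sum cutoff (strict `>`; default 15000).
#' @return character vector of retained gene names, order preserved.
#' @export
filter_genes_pooled_sum <- function(profiles, threshold = 15000) {
  genes <- shared_features(profiles)
  pooled <- Reduce(`+`, lapply(profiles, function(p) colSums(p$expression)))
  genes[pooled > threshold]
}
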