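#' Donor expression profile
#'
#' A `donor_profile` holds one donor's (optionally one condition's)
#' cells-by-features expression matrix together with donor metadata.  It is
#' the basic unit of every workflow in this package: each profile is treated
#' as a finite sample from that donor's cell-population distribution.
#'
#' @param expression numeric matrix, cells in rows, features (markers or
#'   genes) in columns.  Missing values are rejected.
#' @param donor_id single string identifying the donor.
#' @param feature_names optional character vector of feature names; defaults
#'   to `colnames(expression)`.  Must be unique.
#' @param group_label optional group label (e.g. `"case"` / `"control"`).
#' @param condition optional condition / stimulation / tube identifier.
#' @param metadata optional named list of extra metadata.
#'
#' @return An object of class `donor_profile` with elements `expression`,
#'   `donor_id`, `group_label`, `condition`, `feature_names`, `metadata`.
#' @examples
#' dp <- donor_profile(matrix(rnorm(20), 5, 4,
#'                            dimnames = list(NULL, paste0("g", 1:4))), "d1")
#' n_cells(dp); n_features(dp)
#' @export
donor_profile <- function(expression, donor_id, feature_names = NULL,
                          group_label = NULL, condition = NULL,
                          metadata = list()) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (!is.character(donor_id) || length(donor_id) != 1L || is.na(donor_id))
    stop("`donor_id` must be a single string", call. = FALSE)
  if (nrow(expression) < 1L)
    stop("empty profile for donor '", donor_id, "': no cells", call. = FALSE)
  if (anyNA(expression))
    stop("profile for donor '", donor_id, "' contains missing values",
         call. = FALSE)
  if (is.null(feature_names)) feature_names <- colnames(expression)
  if (is.null(feature_names))
    feature_names <- paste0("feature", seq_len(ncol(expression)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(expression))
    stop("feature_names has length ", length(feature_names),
         " but expression has ", ncol(expression), " columns", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "), call. = FALSE)
  colnames(expression) <- feature_names
  structure(list(expression = expression,
                 donor_id = donor_id,
                 group_label = group_label,
                 condition = condition,
                 feature_names = feature_names,
                 metadata = metadata),
            class = "donor_profile")
}

#' @rdname donor_profile
#' @param x a `donor_profile`.
#' @export
n_cells <- function(x) nrow(x$expression)

#' @rdname donor_profile
#' @export
n_features <- function(x) ncol(x$expression)

#' @export
print.donor_profile <- function(x, ...) {
  cat("<donor_profile> ", x$donor_id,
      if (!is.null(x$condition)) paste0(" [", x$condition, "]"),
      ": ", n_cells(x), " cells x ", n_features(x), " features",
      if (!is.null(x$group_label)) paste0(" (group: ", x$group_label, ")"),
      "\n", sep = "")
  invisible(x)
}

# internal: assert a list of donor_profiles shares feature_names, return them
shared_features <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1L]]$feature_names
  for (i in seq_along(profiles)) {
    fn <- profiles[[i]]$feature_names
    if (!identical(fn, ref)) {
      bad <- which(fn != ref[seq_along(fn)])[1L]
      if (is.na(bad)) bad <- min(length(fn), length(ref)) + 1L
      stop("profiles disagree on feature names (first discrepancy at ",
           "position ", bad, ", donor '", profiles[[i]]$donor_id, "')",
           call. = FALSE)
    }
  }
  ref
}
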