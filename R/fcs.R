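#' Read a flow cytometry standard (FCS) file
#'
#' Minimal reader for FCS 2.0 / 3.0 / 3.1 list-mode files covering the data
#' types used by cytometry instruments: 32-bit float (`$DATATYPE F`), 64-bit
#' double (`D`) and unsigned integer (`I`, 16 or 32 bit).  Channel names are
#' taken from the stain keyword `$PnS` when present, falling back to the
#' detector keyword `$PnN` (configurable).  Spillover compensation is out of
#' scope; values are returned exactly as stored.
#'
#' @param path path to a readable FCS file.
#' @param donor_id donor identifier for the returned profile; defaults to the
#'   file name without extension.
#' @param prefer character: which keyword supplies channel names first,
#'   `"PnS"` (stain, default) or `"PnN"` (detector).
#' @return a [donor_profile] with one row per event and one column per
#'   measured channel.
#' @examples
#' f <- tempfile(fileext = ".fcs")
#' write_fcs(matrix(rexp(50), 10, 5), f)
#' read_fcs(f, donor_id = "d1")
#' @export
read_fcs <- function(path, donor_id = NULL, prefer = c("PnS", "PnN")) {
  prefer <- match.arg(prefer)
  if (!file.exists(path))
    stop("FCS file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58)
    stop("not a valid FCS file (too short): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!grepl("^FCS[23]\\.[01]$", version))
    stop("not an FCS 2.0/3.0/3.1 file (bad magic '", version, "'): ", path,
         call. = FALSE)
  off <- suppressWarnings(as.numeric(c(
    substr(header, 11, 18), substr(header, 19, 26),   # text begin/end
    substr(header, 27, 34), substr(header, 35, 42)))) # data begin/end
  if (anyNA(off[1:2]))
    stop("corrupt FCS header offsets in ", path, call. = FALSE)

  seek(con, off[1])
  text_raw <- readChar(con, off[2] - off[1] + 1, useBytes = TRUE)
  delim <- substr(text_raw, 1, 1)
  toks <- strsplit(substring(text_raw, 2), delim, fixed = TRUE)[[1]]
  if (length(toks) < 2)
    stop("empty TEXT segment in ", path, call. = FALSE)
  if (length(toks) %% 2 == 1) toks <- toks[-length(toks)]
  kw <- stats::setNames(trimws(toks[seq(2, length(toks), 2)]),
                        toupper(trimws(toks[seq(1, length(toks), 2)])))

  need <- function(k) {
    v <- unname(kw[k])
    if (is.na(v)) stop("FCS keyword ", k, " missing in ", path,
                       call. = FALSE)
    v
  }
  par <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))
  if (is.na(tot) || tot < 1L)
    stop("empty profile: FCS file ", path, " holds zero events", call. = FALSE)
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  dbeg <- suppressWarnings(as.numeric(unname(kw["$BEGINDATA"])))
  dend <- suppressWarnings(as.numeric(unname(kw["$ENDDATA"])))
  if (is.na(dbeg) || dbeg == 0) dbeg <- off[3]
  if (is.na(dend) || dend == 0) dend <- off[4]

  bits <- as.integer(kw[paste0("$P", seq_len(par), "B")])
  n_values <- par * tot
  seek(con, dbeg)
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8, endian = endian),
    I = {
      if (length(unique(bits)) != 1L)
        stop("mixed $PnB widths unsupported in ", path, call. = FALSE)
      # FCS integers are unsigned; R can only read 32-bit as signed
      readBin(con, "integer", n = n_values, size = bits[1] / 8,
              signed = bits[1] >= 32, endian = endian)
    },
    stop("unsupported $DATATYPE '", dtype, "' in ", path, call. = FALSE))
  if (length(vals) < n_values)
    stop("truncated FCS data segment in ", path, " (expected ", n_values,
         " values, got ", length(vals), ")", call. = FALSE)

  get_kw <- function(k) { v <- unname(kw[k])
    if (is.na(v) || !nzchar(v)) NA_character_ else v }
  pns <- vapply(seq_len(par), function(i) get_kw(paste0("$P", i, "S")), "")
  pnn <- vapply(seq_len(par), function(i) get_kw(paste0("$P", i, "N")), "")
  nms <- if (prefer == "PnS") ifelse(is.na(pns), pnn, pns)
         else ifelse(is.na(pnn), pns, pnn)
  nms[is.na(nms)] <- paste0("channel", which(is.na(nms)))
  # events are stored row-major (one event = one record of PAR values)
  mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  if (is.null(donor_id))
    donor_id <- sub("\\.[^.]*$", "", basename(path))
  donor_profile(mat, donor_id = donor_id, feature_names = make.unique(nms),
                metadata = list(fcs_version = version, path = path))
}

#' Write a minimal FCS 3.0 file
#'
#' Fixture writer used to exercise [read_fcs] and to emit synthetic
#' cytometry cohorts in a standard format.  Writes list-mode FCS 3.0 with
#' 32-bit little-endian floats; it is *not* a general-purpose FCS writer.
#'
#' @param x numeric matrix, events in rows, channels in columns.
#' @param path output path.
#' @param channel_names detector names (`$PnN`); default from `colnames(x)`.
#' @param stain_names optional stain names (`$PnS`); omitted if `NULL`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, channel_names = colnames(x),
                      stain_names = NULL) {
  x <- as.matrix(x)
  if (is.null(channel_names))
    channel_names <- paste0("FL", seq_len(ncol(x)))
  stopifnot(length(channel_names) == ncol(x),
            is.null(stain_names) || length(stain_names) == ncol(x))
  par <- ncol(x); tot <- nrow(x)
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", par, "$TOT", tot, "$NEXTDATA", "0")
  for (i in seq_len(par)) {
    kv <- c(kv, paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), format(ceiling(max(1, max(x[, i]))),
                                         scientific = FALSE),
            paste0("$P", i, "N"), channel_names[i])
    if (!is.null(stain_names))
      kv <- c(kv, paste0("$P", i, "S"), stain_names[i])
  }
  n_bytes_data <- 4L * par * tot
  # iterate: offsets appear inside TEXT, so build TEXT until stable
  text_begin <- 58L
  data_begin <- 0L
  for (pass in 1:3) {
    kv_full <- c(kv, "$BEGINDATA", data_begin,
                 "$ENDDATA", data_begin + n_bytes_data - 1L)
    text <- paste0("/", paste(kv_full, collapse = "/"), "/")
    text_end <- text_begin + nchar(text, type = "bytes") - 1L
    data_begin_new <- text_end + 1L
    if (data_begin_new == data_begin) break
    data_begin <- data_begin_new
  }
  data_end <- data_begin + n_bytes_data - 1L
  pad <- function(n) formatC(n, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad(text_begin), pad(text_end),
                   if (data_end <= 99999999) paste0(pad(data_begin),
                                                    pad(data_end))
                   else paste0(pad(0), pad(0)),
                   pad(0), pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}
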