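#' Summarize IBD segments per pair of individuals
#'
#' Collapses a segment table into one row per unordered pair with the total
#' length (`sum_cM`), longest segment (`max_cM`) and number of retained
#' segments (`n_segments`).
#'
#' @param segments A segment table (see [ibd-segments]); typically already
#'   merged and filtered.
#' @return A data frame with columns `id_a`, `id_b`, `sum_cM`, `max_cM`,
#'   `n_segments`, one row per pair with at least one segment.
#' @export
summarize_pairs <- function(segments) {
  segments <- validate_segments(segments)
  if (nrow(segments) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      sum_cM = numeric(), max_cM = numeric(),
                      n_segments = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(segments$id_a, segments$id_b, sep = "\r")
  sums <- tapply(segments$length_cM, key, sum)
  maxs <- tapply(segments$length_cM, key, max)
  ns <- tapply(segments$length_cM, key, length)
  ids <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  out <- data.frame(id_a = ids[, 1L], id_b = ids[, 2L],
                    sum_cM = as.numeric(sums), max_cM = as.numeric(maxs),
                    n_segments = as.integer(ns), stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the symmetric pairwise total-IBD matrix
#'
#' @param summaries Per-pair summaries from [summarize_pairs()].
#' @param ids Character vector of individual identifiers defining the matrix
#'   order (a superset of the ids in `summaries`); alternatively a metadata
#'   data frame with an `iid` column.
#' @return A symmetric numeric matrix of total shared IBD (cM) with zero
#'   diagonal and `ids` as dimnames. Pairs with no retained segment are 0.
#' @export
build_ibd_matrix <- function(summaries, ids) {
  if (is.data.frame(ids)) {
    if (!"iid" %in% names(ids)) stop("metadata must have an 'iid' column")
    ids <- ids$iid
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  unknown <- setdiff(unique(c(summaries$id_a, summaries$id_b)), ids)
  if (length(unknown)) {
    stop("segment summaries reference unknown individual(s): ",
         paste(unknown, collapse = ", "))
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(summaries)) {
    i <- match(summaries$id_a, ids)
    j <- match(summaries$id_b, ids)
    m[cbind(i, j)] <- summaries$sum_cM
    m[cbind(j, i)] <- summaries$sum_cM
  }
  m
}

#' Check an object is a valid pairwise IBD matrix
#'
#' Asserts the matrix contract: square, numeric, symmetric, non-negative,
#' zero diagonal, with individual ids as dimnames.
#'
#' @param m Matrix to check.
#' @param tol Symmetry tolerance.
#' @return `m`, invisibly, or an error.
#' @export
validate_ibd_matrix <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) != ncol(m)) stop("IBD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("IBD matrix must carry identical row and column ids")
  }
  if (any(abs(m - t(m)) > tol)) stop("IBD matrix is not symmetric")
  if (any(diag(m) != 0)) stop("IBD matrix diagonal must be zero")
  if (any(m < 0)) stop("IBD matrix entries must be non-negative")
  invisible(m)
}

#' Read / write a pairwise IBD matrix as CSV
#'
#' The CSV carries individual ids as both the header row and the first
#' column, with a numeric body.
#'
#' @param path File path.
#' @return `read_ibd_matrix` returns a validated matrix;
#'   `write_ibd_matrix` returns `path` invisibly.
#' @export
read_ibd_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_ibd_matrix(m)
  m
}

#' @rdname read_ibd_matrix
#' @param m A pairwise IBD matrix.
#' @export
write_ibd_matrix <- function(m, path) {
  validate_ibd_matrix(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read an individual metadata table
#'
#' Tab-separated with columns
#' `iid group region lat lon date_lo date_hi sex`; `group` is the mortuary
#' affiliation (e.g. DSKC, FigureShaped, SlabGrave), `region` a geographic
#' label, `lat`/`lon` site coordinates in degrees, and `date_lo`/`date_hi`
#' a calibrated interval in years BCE (metadata only).
#'
#' @param path Path to a tab-separated metadata file.
#' @return A data frame with the columns above.
#' @export
read_individuals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("iid", "group", "region", "lat", "lon")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$iid)) stop("duplicated individual ids in metadata")
  ok <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  if (!all(ok)) stop("latitude out of [-90, 90]")
  ok <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  if (!all(ok)) stop("longitude out of [-180, 180]")
  df
}

#' End-to-end matrix construction from files
#'
#' Convenience wrapper: read segments and metadata, merge adjacent
#' IBD1/IBD2 calls, apply the length/density filter, and build the
#' pairwise total-IBD matrix over all individuals in the metadata.
#'
#' @param segments_path Segment TSV (see [read_ibd_segments()]).
#' @param meta_path Metadata TSV (see [read_individuals()]).
#' @param min_len_cM,min_density Filter thresholds, see [filter_segments()].
#' @param gap_tol_cM Merge tolerance, see [merge_adjacent_states()].
#' @return A pairwise IBD matrix.
#' @export
ibd_matrix_from_files <- function(segments_path, meta_path,
                                  min_len_cM = 12, min_density = 220,
                                  gap_tol_cM = 0) {
  segs <- read_ibd_segments(segments_path)
  meta <- read_individuals(meta_path)
  segs <- merge_adjacent_states(segs, gap_tol_cM = gap_tol_cM)
  segs <- filter_segments(segs, min_len_cM = min_len_cM,
                          min_density = min_density)
  build_ibd_matrix(summarize_pairs(segs), meta)
}
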