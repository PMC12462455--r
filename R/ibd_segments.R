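#' @title IBD segment tables
#' @description
#' An IBD segment table is a plain data frame with one row per called IBD
#' block per pair of individuals, in genetic-map coordinates:
#' `id_a`, `id_b` (individual identifiers, lexicographically ordered so that
#' unordered pairs have a canonical representation), `chrom` (autosome 1-22),
#' `start_cM` / `end_cM` (half-open genetic interval), `length_cM`,
#' `n_snps` (panel SNPs spanned) and `state` (`"IBD1"` or `"IBD2"`).
#' @name ibd-segments
NULL

SEGMENT_COLS <- c("id_a", "id_b", "chrom", "start_cM", "end_cM",
                  "length_cM", "n_snps", "state")

#' Validate an IBD segment table
#'
#' Checks the segment invariants (`end_cM > start_cM`, `length_cM` equal to
#' the interval length within tolerance, `n_snps >= 0`, `id_a != id_b`)
#' and canonicalizes pair order so that `id_a < id_b`.
#'
#' @param segments Data frame with the columns described in [ibd-segments].
#' @param tol Tolerance for the `length_cM == end_cM - start_cM` check.
#' @return The validated, pair-normalized segment table.
#' @export
validate_segments <- function(segments, tol = 1e-6) {
  stopifnot(is.data.frame(segments))
  missing_cols <- setdiff(SEGMENT_COLS, names(segments))
  if (length(missing_cols)) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  segments <- segments[, SEGMENT_COLS]
  if (nrow(segments) == 0L) return(segments)
  segments$id_a <- as.character(segments$id_a)
  segments$id_b <- as.character(segments$id_b)
  bad <- which(!(segments$end_cM > segments$start_cM))
  if (length(bad)) {
    stop("end_cM <= start_cM at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(abs(segments$length_cM -
                     (segments$end_cM - segments$start_cM)) > tol)
  if (length(bad)) {
    stop("length_cM inconsistent with end_cM - start_cM at row(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(segments$n_snps < 0)
  if (length(bad)) stop("negative n_snps at row(s): ", paste(bad, collapse = ", "))
  bad <- which(segments$id_a == segments$id_b)
  if (length(bad)) {
    stop("id_a == id_b (self pair) at row(s): ", paste(bad, collapse = ", "))
  }
  if (!all(segments$state %in% c("IBD1", "IBD2"))) {
    stop("state must be 'IBD1' or 'IBD2'")
  }
  swap <- segments$id_a > segments$id_b
  if (any(swap)) {
    tmp <- segments$id_a[swap]
    segments$id_a[swap] <- segments$id_b[swap]
    segments$id_b[swap] <- tmp
  }
  rownames(segments) <- NULL
  segments
}

#' Read an IBD segment table from a TSV file
#'
#' The file must carry a header with columns
#' `iid1 iid2 ch start_cM end_cM length_cM n_snps state`
#' (the naming convention of ancIBD-style output).
#'
#' @param path Path to a tab-separated segment file.
#' @return A validated segment table (see [ibd-segments]).
#' @export
read_ibd_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ext <- c(iid1 = "id_a", iid2 = "id_b", ch = "chrom")
  for (nm in names(ext)) {
    if (nm %in% names(df)) names(df)[names(df) == nm] <- ext[[nm]]
  }
  missing_cols <- setdiff(SEGMENT_COLS, names(df))
  if (length(missing_cols)) {
    stop("segment file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("start_cM", "end_cM", "length_cM")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$n_snps <- as.integer(df$n_snps)
  validate_segments(df)
}

#' Write an IBD segment table to a TSV file
#'
#' Inverse of [read_ibd_segments()]: columns are written under the external
#' names `iid1 iid2 ch start_cM end_cM length_cM n_snps state`.
#'
#' @param segments A validated segment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  segments <- validate_segments(segments)
  out <- segments
  names(out)[match(c("id_a", "id_b", "chrom"), names(out))] <-
    c("iid1", "iid2", "ch")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge adjacent IBD1/IBD2 segments
#'
#' IBD callers that emit separate IBD1 and IBD2 state calls fragment what is
#' biologically one shared block. For each pair and chromosome, runs of
#' segments whose gap is at most `gap_tol_cM` are replaced by a single
#' segment spanning `min(start)` to `max(end)`; SNP counts are summed and the
#' merged state is `IBD1` if any constituent was IBD1, else `IBD2`.
#' Overlapping segments are merged likewise, with a warning (double-counted
#' SNPs are not corrected).
#'
#' @param segments A segment table (see [ibd-segments]).
#' @param gap_tol_cM Maximum gap (cM) between segments that still merges;
#'   default 0 (strict adjacency).
#' @return A segment table with no two same-pair/same-chromosome segments
#'   closer than `gap_tol_cM`.
#' @export
merge_adjacent_states <- function(segments, gap_tol_cM = 0) {
  stopifnot(gap_tol_cM >= 0)
  segments <- validate_segments(segments)
  if (nrow(segments) <= 1L) return(segments)
  key <- paste(segments$id_a, segments$id_b, segments$chrom, sep = "\r")
  pieces <- split(segments, key)
  warned <- FALSE
  out <- lapply(pieces, function(df) {
    df <- df[order(df$start_cM), , drop = FALSE]
    if (nrow(df) == 1L) return(df)
    gap <- df$start_cM[-1L] - df$end_cM[-nrow(df)]
    if (!warned && any(gap < 0)) {
      warned <<- TRUE
      warning("overlapping segments for the same pair/chromosome were merged; ",
              "SNP counts in the overlap are double-counted")
    }
    grp <- cumsum(c(0, as.integer(gap > gap_tol_cM)))
    res <- lapply(split(df, grp), function(run) {
      data.frame(
        id_a = run$id_a[1L], id_b = run$id_b[1L], chrom = run$chrom[1L],
        start_cM = min(run$start_cM), end_cM = max(run$end_cM),
        length_cM = max(run$end_cM) - min(run$start_cM),
        n_snps = sum(run$n_snps),
        state = if (any(run$state == "IBD1")) "IBD1" else "IBD2",
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$id_a, out$id_b, out$chrom, out$start_cM), , drop = FALSE]
}

#' Filter IBD segments by length and SNP density
#'
#' Retains segments with `length_cM >= min_len_cM` and
#' `n_snps / length_cM >= min_density`. Both thresholds are inclusive; the
#' defaults (12 cM, 220 SNPs/cM on a 1240K-style panel) are the standard
#' post-calling filter against false-positive blocks in imputed ancient
#' genomes.
#'
#' @param segments A segment table.
#' @param min_len_cM Minimum genetic length in cM (inclusive).
#' @param min_density Minimum SNPs per cM (inclusive). Set to 0 to filter on
#'   length only (as for simulated segments with no genotype panel).
#' @return The retained segments, input order preserved.
#' @export
filter_segments <- function(segments, min_len_cM = 12, min_density = 220) {
  segments <- validate_segments(segments)
  keep <- segments$length_cM >= min_len_cM &
    segments$n_snps / segments$length_cM >= min_density
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
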