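#' Mean pairwise IBD within or between groups
#'
#' The group-level sharing statistic: total shared IBD divided by the number
#' of *possible* pairs, so pairs sharing nothing contribute zeros to the
#' denominator. Within a group the denominator is `n(n-1)/2`; between two
#' disjoint groups it is `n_a * n_b`.
#'
#' @param m A pairwise IBD matrix (see [validate_ibd_matrix()]).
#' @param group_a Character vector of ids.
#' @param group_b Optional second id set; if `NULL` or identical to
#'   `group_a`, the within-group mean is computed.
#' @return A list with `mean_cM`, `total_cM` and `n_pairs`.
#' @export
mean_pair_ibd <- function(m, group_a, group_b = NULL) {
  validate_ibd_matrix(m)
  group_a <- as.character(group_a)
  if (!length(group_a)) stop("group_a is empty")
  missing_ids <- setdiff(group_a, rownames(m))
  if (length(missing_ids)) {
    stop("ids not in matrix: ", paste(missing_ids, collapse = ", "))
  }
  within <- is.null(group_b) || setequal(group_b, group_a)
  if (within) {
    if (length(group_a) < 2L) stop("within-group mean needs >= 2 individuals")
    sub <- m[group_a, group_a, drop = FALSE]
    n_pairs <- length(group_a) * (length(group_a) - 1L) / 2
    total <- sum(sub) / 2
  } else {
    group_b <- as.character(group_b)
    missing_ids <- setdiff(group_b, rownames(m))
    if (length(missing_ids)) {
      stop("ids not in matrix: ", paste(missing_ids, collapse = ", "))
    }
    if (length(intersect(group_a, group_b))) {
      stop("distinct groups must be disjoint")
    }
    n_pairs <- length(group_a) * length(group_b)
    total <- sum(m[group_a, group_b, drop = FALSE])
  }
  list(mean_cM = total / n_pairs, total_cM = total, n_pairs = n_pairs)
}

#' Within- versus between-group IBD sharing statistic
#'
#' The replacement-model test statistic: the mean within-group sharing
#' (averaged across the two groups) minus the mean between-group sharing,
#' `(w1 + w2)/2 - b`. Positive values indicate IBD enrichment within groups,
#' i.e. limited gene flow between them.
#'
#' @param m A pairwise IBD matrix.
#' @param labels Named character/factor vector mapping each id in `m` (or a
#'   subset) to one of exactly two group labels; each group needs >= 2
#'   members.
#' @return The statistic in cM.
#' @export
within_between_stat <- function(m, labels) {
  validate_ibd_matrix(m)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by individual id")
  groups <- split(names(labels), labels)
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 members")
  w1 <- mean_pair_ibd(m, groups[[1L]])$mean_cM
  w2 <- mean_pair_ibd(m, groups[[2L]])$mean_cM
  b <- mean_pair_ibd(m, groups[[1L]], groups[[2L]])$mean_cM
  (w1 + w2) / 2 - b
}

#' Local-continuity enrichment ratio
#'
#' The double ratio `(FcSc/FcSo) / (FeSc/FeSo)` contrasting the sharing of a
#' focal-region source group (Fc) with the focal-region successor group (Sc)
#' against the same contrast for an outside source group (Fe), each
#' normalized by sharing with successors from outside the focal region (So)
#' to control for the background IBD level. Values well above 1 indicate
#' local genetic continuity; values near or below 1 indicate replacement.
#'
#' Zero denominators are replaced by `zero_sub` (default 0.01 cM) before
#' dividing, mirroring standard practice in sparse ancient-DNA matrices.
#'
#' @param fcsc,fcso,fesc,feso Mean pairwise IBD (cM) for the four group
#'   pairs; all must be >= 0.
#' @param zero_sub Substitution value for zero denominators.
#' @return A list with `ratio` and `n_substituted`.
#' @export
continuity_ratio <- function(fcsc, fcso, fesc, feso, zero_sub = 0.01) {
  vals <- c(fcsc, fcso, fesc, feso)
  if (any(vals < 0)) stop("group means must be non-negative")
  n_sub <- 0L
  if (fcso == 0) { fcso <- zero_sub; n_sub <- n_sub + 1L }
  if (feso == 0) { feso <- zero_sub; n_sub <- n_sub + 1L }
  denom <- fesc / feso
  if (denom == 0) { denom <- zero_sub; n_sub <- n_sub + 1L }
  list(ratio = (fcsc / fcso) / denom, n_substituted = n_sub)
}

#' Empirical p-value of a permutation null
#'
#' `p = #(null >= observed) / N`, ties counting as exceedances, with no
#' `(k+1)/(N+1)` smoothing: the observed labeling is not force-included in
#' the null.
#'
#' @param null_values Numeric vector of permutation statistics.
#' @param observed Observed statistic.
#' @return Empirical p in `[0, 1]`.
#' @export
empirical_p <- function(null_values, observed) {
  if (!length(null_values)) stop("empty null distribution")
  sum(null_values >= observed) / length(null_values)
}
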