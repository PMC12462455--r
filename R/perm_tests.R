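#' @title Permutation tests on pairwise IBD matrices
#' @description
#' Three seeded permutation procedures for distinguishing population
#' replacement from cultural diffusion with pairwise total-IBD matrices:
#' label shuffling of the full symmetric matrix, column permutation of a
#' source-by-successor sub-matrix, and exhaustive row permutation of the
#' same sub-matrix. All return a `perm_test` object holding the observed
#' statistic, the null distribution, and the empirical p-value
#' (proportion of null values >= observed; see [empirical_p()]).
#' Permutations are independent uniform draws (sampling the relabeling
#' space with replacement); exhaustive mode is seed-independent.
#' @name perm-tests
NULL

perm_result <- function(statistic, observed, null, seed, n_substituted = 0L,
                        extra = list()) {
  res <- c(list(
    statistic = statistic,
    observed = observed,
    null = null,
    n_perm = length(null),
    p = empirical_p(null, observed),
    seed = seed,
    n_substituted = n_substituted
  ), extra)
  class(res) <- "perm_test"
  res
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", x$statistic, "\n")
  cat(sprintf("  observed = %.6g\n", x$observed))
  cat(sprintf("  permutations = %d (%s)\n", x$n_perm,
              if (identical(x$seed, "exhaustive")) "exhaustive"
              else paste0("seed ", x$seed)))
  if (x$n_substituted > 0)
    cat(sprintf("  zero-denominator substitutions = %d\n", x$n_substituted))
  cat(sprintf("  empirical p = %.4g\n", x$p))
  invisible(x)
}

#' Label-shuffle test of within- versus between-group IBD enrichment
#'
#' Tests whether two groups each share more IBD internally than with each
#' other. The statistic is [within_between_stat()]; each permutation draws a
#' uniform random relabeling of the individuals with the original group
#' sizes while the matrix values stay untouched.
#'
#' @param m A pairwise IBD matrix.
#' @param labels Named two-group labeling of (a subset of) the matrix ids;
#'   each group needs >= 2 members.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A `perm_test` object.
#' @export
label_shuffle_test <- function(m, labels, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  validate_ibd_matrix(m)
  if (is.null(names(labels))) stop("labels must be named by individual id")
  ids <- names(labels)
  if (length(setdiff(ids, rownames(m)))) {
    stop("labels reference ids missing from the matrix")
  }
  observed <- within_between_stat(m, labels)
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(labels)
  sub <- m[ids, ids, drop = FALSE]
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(lab)
    within_between_stat(sub, stats::setNames(perm, ids))
  }, numeric(1))
  perm_result("within_between", observed, null, seed)
}

fig_slab_means <- function(fs, fc_rows, sc_cols) {
  fe_rows <- setdiff(rownames(fs), fc_rows)
  so_cols <- setdiff(colnames(fs), sc_cols)
  c(fcsc = mean(fs[fc_rows, sc_cols, drop = FALSE]),
    fcso = mean(fs[fc_rows, so_cols, drop = FALSE]),
    fesc = mean(fs[fe_rows, sc_cols, drop = FALSE]),
    feso = mean(fs[fe_rows, so_cols, drop = FALSE]))
}

#' Column-permutation test for local genetic continuity
#'
#' Operates on a rectangular source-by-successor IBD sub-matrix (rows:
#' source-tradition individuals split into focal-region `Fc` and outside
#' `Fe`; columns: all successor-tradition individuals). The statistic is the
#' continuity enrichment `(FcSc/FcSo)/(FeSc/FeSo)` (see
#' [continuity_ratio()]) computed from the current column assignment into
#' focal-region `Sc` versus outside `So`. Each permutation uniformly
#' reassigns columns to `Sc` (keeping its size), leaving each column's IBD
#' combination intact. Large observed values relative to the null indicate
#' genetic continuity in the focal region; an unremarkable observed value
#' supports replacement.
#'
#' @param fs Numeric matrix, rows = source individuals, columns = successor
#'   individuals, entries = total pairwise IBD (cM); dimnames required.
#' @param fc_rows Row ids forming the focal-region source group `Fc`.
#' @param sc_cols Column ids forming the observed focal-region successor
#'   group `Sc`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param zero_sub Zero-denominator substitution (cM).
#' @return A `perm_test` object.
#' @export
continuity_test <- function(fs, fc_rows, sc_cols, n_perm = 10000,
                            seed = NULL, zero_sub = 0.01) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(is.matrix(fs), !is.null(rownames(fs)), !is.null(colnames(fs)))
  fc_rows <- as.character(fc_rows)
  sc_cols <- as.character(sc_cols)
  if (length(setdiff(fc_rows, rownames(fs)))) stop("unknown Fc row id")
  if (length(setdiff(sc_cols, colnames(fs)))) stop("unknown Sc column id")
  sc_size <- length(sc_cols)
  if (sc_size < 1L || sc_size >= ncol(fs)) {
    stop("Sc size must be in [1, n_columns - 1]")
  }
  if (length(fc_rows) < 1L || length(fc_rows) >= nrow(fs)) {
    stop("Fc size must be in [1, n_rows - 1]")
  }
  stat_of <- function(cols) {
    mm <- fig_slab_means(fs, fc_rows, cols)
    continuity_ratio(mm[["fcsc"]], mm[["fcso"]], mm[["fesc"]], mm[["feso"]],
                     zero_sub = zero_sub)
  }
  obs <- stat_of(sc_cols)
  n_sub <- obs$n_substituted
  if (!is.null(seed)) set.seed(seed)
  all_cols <- colnames(fs)
  null <- vapply(seq_len(n_perm), function(i) {
    r <- stat_of(sample(all_cols, sc_size))
    n_sub <<- n_sub + r$n_substituted
    r$ratio
  }, numeric(1))
  perm_result("continuity_ratio", obs$ratio, null, seed, n_sub)
}

#' Row-permutation test of differential source-group contribution
#'
#' Tests whether the outside source group `Fe` contributed more to the
#' successor population than the focal-region source group `Fc`: the
#' statistic is `FeS/FcS`, the ratio of mean IBD shared with *all*
#' successor individuals. Permutations reassign rows to `Fc` (keeping its
#' size); in exhaustive mode every one of the `choose(n_rows, |Fc|)`
#' assignments is enumerated, which makes the null distribution
#' seed-independent. Zero denominators (`FcS = 0`) are substituted with
#' `zero_sub` before dividing; such permutations are flagged but retained in
#' the p-value count.
#'
#' @param fs Source-by-successor IBD matrix, as in [continuity_test()].
#' @param fc_rows Row ids forming the observed `Fc` group.
#' @param mode `"exhaustive"` (default when feasible) or `"sampled"`.
#' @param n_perm Number of permutations for sampled mode.
#' @param seed Optional integer seed (sampled mode only).
#' @param zero_sub Zero-denominator substitution (cM).
#' @param max_exhaustive Refuse exhaustive enumeration above this many
#'   assignments.
#' @return A `perm_test` object; in exhaustive mode `seed` is the string
#'   `"exhaustive"` and the element `extreme` flags null values larger than
#'   100 times the median (artifacts of denominator substitution, kept in
#'   the p-value but usually excluded from plots).
#' @export
contribution_test <- function(fs, fc_rows, mode = c("exhaustive", "sampled"),
                              n_perm = 10000, seed = NULL, zero_sub = 0.01,
                              max_exhaustive = 1e6) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(fs), !is.null(rownames(fs)))
  fc_rows <- as.character(fc_rows)
  if (length(setdiff(fc_rows, rownames(fs)))) stop("unknown Fc row id")
  n_rows <- nrow(fs)
  k <- length(fc_rows)
  if (k < 1L || k >= n_rows) stop("Fc size must be in [1, n_rows - 1]")
  row_means <- rowMeans(fs) # mean IBD of each source row with all successors
  n_sub <- 0L
  stat_of <- function(fc_idx) {
    fcs <- mean(row_means[fc_idx])
    fes <- mean(row_means[-fc_idx])
    if (fcs == 0) { fcs <- zero_sub; n_sub <<- n_sub + 1L }
    fes / fcs
  }
  obs_idx <- match(fc_rows, rownames(fs))
  observed <- stat_of(obs_idx)
  if (mode == "exhaustive") {
    n_assign <- choose(n_rows, k)
    if (n_assign > max_exhaustive) {
      stop("exhaustive enumeration of ", n_assign, " assignments exceeds the ",
           "cap (", max_exhaustive, "); use mode = 'sampled'")
    }
    combos <- utils::combn(n_rows, k)
    null <- apply(combos, 2L, stat_of)
    seed_out <- "exhaustive"
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      stat_of(sample.int(n_rows, k))
    }, numeric(1))
    seed_out <- seed
  }
  extreme <- which(null > 100 * stats::median(null))
  perm_result("contribution_ratio", observed, null, seed_out, n_sub,
              extra = list(extreme = extreme))
}
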