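#' Sex-biased admixture Z score
#'
#' Contrasts the admixture proportion of an ancestry source estimated on the
#' autosomes with the estimate on the X chromosome:
#' `z = (P_A - P_X) / sqrt(sigma_A^2 + sigma_X^2)`,
#' where the sigmas are jackknife standard errors. Because females carry two
#' X chromosomes and males one, an ancestry overrepresented on the autosomes
#' relative to the X (positive z) indicates a male-biased contribution of
#' that ancestry; a negative z indicates a female-biased contribution.
#'
#' Proportions outside `[0, 1]` are admitted with a warning (unconstrained
#' f-statistics fits can step outside the simplex). Vectorized.
#'
#' @param P_A,P_X Admixture proportions on autosomes and X chromosome.
#' @param sigma_A,sigma_X Corresponding jackknife standard errors (> 0).
#' @return Numeric z score(s).
#' @export
sexbias_z <- function(P_A, sigma_A, P_X, sigma_X) {
  if (any(sigma_A <= 0) || any(sigma_X <= 0)) {
    stop("standard errors must be > 0")
  }
  if (any(c(P_A, P_X) < 0 | c(P_A, P_X) > 1)) {
    warning("admixture proportion outside [0, 1]")
  }
  (P_A - P_X) / sqrt(sigma_A^2 + sigma_X^2)
}

#' Sex-bias table helper
#'
#' Applies [sexbias_z()] to a table of ancestry estimates and appends the z
#' score plus a two-sided normal p-value (a reporting aid, not a calibrated
#' test).
#'
#' @param est Data frame with columns `P_A`, `sigma_A`, `P_X`, `sigma_X`
#'   (additional columns such as `target`/`source` pass through).
#' @return `est` with columns `z` and `p_normal` appended.
#' @export
sexbias_table <- function(est) {
  stopifnot(all(c("P_A", "sigma_A", "P_X", "sigma_X") %in% names(est)))
  est$z <- sexbias_z(est$P_A, est$sigma_A, est$P_X, est$sigma_X)
  est$p_normal <- 2 * stats::pnorm(-abs(est$z))
  est
}
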