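#' Pairwise mismatch rate of pseudo-haploid genotypes
#'
#' The pmr is the fraction of jointly covered panel sites at which two
#' pseudo-haploid genotype vectors disagree. With one randomly sampled
#' allele per site, unrelated individuals mismatch at about
#' `2 * E[p(1 - p)]` of sites (the mean panel heterozygosity) and the rate
#' drops linearly with relatedness, which is what makes pmr a usable
#' kinship statistic at very low coverage.
#'
#' @param geno_a,geno_b Equal-length vectors of 0/1 allele codes with
#'   `missing` marking uncovered sites.
#' @param missing Missing-data code (default `9L`).
#' @return List with `pmr` (mismatch fraction) and `n_overlap` (jointly
#'   covered sites). Zero overlap is an error.
#' @export
pmr <- function(geno_a, geno_b, missing = 9L) {
  if (length(geno_a) != length(geno_b)) stop("genotype vectors differ in length")
  ok <- geno_a != missing & geno_b != missing
  n_overlap <- sum(ok)
  if (n_overlap == 0L) stop("no jointly covered sites; pmr undefined")
  list(pmr = sum(geno_a[ok] != geno_b[ok]) / n_overlap, n_overlap = n_overlap)
}

#' All pairwise mismatch rates of a genotype matrix
#'
#' @param genos Matrix of 0/1/`missing` pseudo-haploid calls, individuals in
#'   columns, sites in rows.
#' @param missing Missing-data code.
#' @param min_overlap Pairs with fewer jointly covered sites get `NA` pmr.
#' @return Data frame with `id_a`, `id_b`, `pmr`, `n_overlap` per pair.
#' @export
pmr_matrix <- function(genos, missing = 9L, min_overlap = 1L) {
  stopifnot(is.matrix(genos))
  ids <- colnames(genos)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(genos)))
  idx <- utils::combn(ncol(genos), 2L)
  res <- apply(idx, 2L, function(ij) {
    a <- genos[, ij[1L]]; b <- genos[, ij[2L]]
    ok <- a != missing & b != missing
    n <- sum(ok)
    c(if (n >= min_overlap && n > 0L) sum(a[ok] != b[ok]) / n else NA_real_, n)
  })
  data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
             pmr = res[1L, ], n_overlap = as.integer(res[2L, ]),
             stringsAsFactors = FALSE)
}

#' Baseline (unrelated-pair) pmr from the density mode
#'
#' In a cohort where most pairs are unrelated, the pmr values pile up at the
#' unrelated expectation; close relatives form a thin left tail that barely
#' moves the mode. The baseline is therefore estimated as the mode of a
#' Gaussian kernel density (Silverman bandwidth, 512-point grid spanning the
#' data).
#'
#' @param pmr_values Numeric vector of pairwise mismatch rates (>= 10
#'   values required).
#' @return The baseline pmr (density mode).
#' @export
estimate_baseline <- function(pmr_values) {
  pmr_values <- pmr_values[!is.na(pmr_values)]
  if (length(pmr_values) < 10L) {
    stop("need >= 10 pmr values to estimate a baseline; ",
         "supply a manual baseline instead")
  }
  if (stats::sd(pmr_values) == 0) return(pmr_values[1L])
  d <- stats::density(pmr_values, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Kinship coefficient from pmr
#'
#' `coefficient = 1 - pmr / baseline`: 0 for unrelated pairs, 1/4 for
#' first-degree relatives (pmr at 3/4 of baseline), 1/8 for second degree
#' (7/8 of baseline), 1/16 for third degree (15/16 of baseline), and 1/2
#' for identical individuals/twins.
#'
#' @param pmr Pairwise mismatch rate(s).
#' @param baseline Unrelated-pair baseline (> 0), see [estimate_baseline()].
#' @return Kinship coefficient(s), `<= 1`.
#' @export
kinship_coefficient <- function(pmr, baseline) {
  if (baseline <= 0) stop("baseline must be > 0")
  1 - pmr / baseline
}

#' Relatedness degree from a kinship coefficient
#'
#' Bins are centred on the expected coefficients 1/2 (identical), 1/4
#' (1st degree), 1/8 (2nd), 1/16 (3rd), with geometric-midpoint boundaries
#' `2^-1.5, 2^-2.5, 2^-3.5, 2^-4.5`; coefficients at or below `2^-4.5` are
#' called unrelated. Pairs with fewer than `min_overlap` jointly covered
#' sites are called `low-confidence` regardless of the coefficient.
#'
#' @param coefficient Kinship coefficient(s) from [kinship_coefficient()].
#' @param n_overlap Jointly covered site count(s) (default `Inf`).
#' @param min_overlap Minimum overlap for a confident call (default 5000).
#' @param breaks Bin boundaries, highest first; override to tune binning.
#' @return Character vector of degree calls.
#' @export
classify_degree <- function(coefficient, n_overlap = Inf, min_overlap = 5000,
                            breaks = 2^-(c(1.5, 2.5, 3.5, 4.5))) {
  stopifnot(length(breaks) == 4L, all(diff(breaks) < 0))
  call_one <- function(k) {
    if (k > breaks[1L]) "identical"
    else if (k > breaks[2L]) "1st"
    else if (k > breaks[3L]) "2nd"
    else if (k > breaks[4L]) "3rd"
    else "unrelated"
  }
  out <- vapply(coefficient, call_one, character(1))
  out[rep_len(n_overlap, length(out)) < min_overlap] <- "low-confidence"
  out
}

#' Kinship estimates for all pairs of a genotype matrix
#'
#' Convenience pipeline: pairwise pmr, density-mode baseline over all pairs,
#' kinship coefficients and degree calls.
#'
#' @inheritParams pmr_matrix
#' @param min_overlap Minimum overlap for a confident degree call.
#' @param baseline Optional manual baseline; estimated from the data when
#'   `NULL`.
#' @return Data frame with per-pair `pmr`, `n_overlap`, `coefficient`,
#'   `degree`, plus the `baseline` as an attribute.
#' @export
kinship_from_genotypes <- function(genos, missing = 9L, min_overlap = 5000,
                                   baseline = NULL) {
  pm <- pmr_matrix(genos, missing = missing)
  if (is.null(baseline)) baseline <- estimate_baseline(pm$pmr)
  pm$coefficient <- kinship_coefficient(pm$pmr, baseline)
  pm$degree <- classify_degree(pm$coefficient, pm$n_overlap, min_overlap)
  attr(pm, "baseline") <- baseline
  pm
}

#' Fit a relationship envelope from simulated replicates
#'
#' Summarizes the per-replicate `(sum_cM, n_segments)` cloud of one pedigree
#' relationship by a bivariate normal (mean vector and covariance matrix),
#' which turns the visual scatter comparison into a testable likelihood
#' rule.
#'
#' @param relationship Relationship label.
#' @param replicates Data frame with columns `sum_cM`, `n_segments`.
#' @return An object of class `relationship_envelope` with fields
#'   `relationship`, `replicates`, `mean`, `cov` and `usable` (FALSE when
#'   all replicates are zero, in which case the envelope is excluded from
#'   likelihood ranking).
#' @export
fit_envelope <- function(relationship, replicates) {
  stopifnot(all(c("sum_cM", "n_segments") %in% names(replicates)))
  x <- cbind(replicates$sum_cM, replicates$n_segments)
  mu <- colMeans(x)
  usable <- nrow(x) >= 3L && any(x[, 1L] > 0) && all(diag(stats::cov(x)) > 0)
  structure(list(relationship = relationship,
                 replicates = replicates,
                 mean = mu,
                 cov = if (usable) stats::cov(x) else NULL,
                 usable = usable),
            class = "relationship_envelope")
}

envelope_loglik <- function(env, sum_cM, n_segments) {
  if (!env$usable) return(-Inf)
  d <- c(sum_cM, n_segments) - env$mean
  cv <- env$cov
  # ridge for near-singular clouds (e.g. parent-child: constant sum)
  eps <- 1e-8 * (diag(cv) + 1)
  cv <- cv + diag(eps, 2L)
  q <- as.numeric(d %*% solve(cv, d))
  -0.5 * (q + log(det(cv)) + 2 * log(2 * pi))
}

#' Classify an observed IBD pair against relationship envelopes
#'
#' Ranks the candidate pedigree relationships by the bivariate-normal
#' log-likelihood of the observed (total IBD, segment count) point. The
#' call is the top-ranked relationship together with every relationship
#' within `window` log-units of it (interval calls such as "3rd to 5th
#' degree"). If the observation lies outside every envelope's 99.9%
#' Mahalanobis region, the call is `"unrelated/beyond 5th degree"`.
#'
#' @param sum_cM Observed total IBD (filtered segments), cM.
#' @param n_segments Observed number of filtered segments.
#' @param envelopes List of [fit_envelope()] objects.
#' @param window Log-likelihood window for the interval call (default 2).
#' @return List with `call` (character vector of relationships in the
#'   interval call, or the unrelated sentinel), and `ranking` (data frame of
#'   relationship, log-likelihood, Mahalanobis distance, sorted).
#' @export
classify_relationship <- function(sum_cM, n_segments, envelopes, window = 2) {
  usable <- Filter(function(e) e$usable, envelopes)
  if (!length(usable)) stop("no usable envelopes")
  ll <- vapply(usable, envelope_loglik, numeric(1),
               sum_cM = sum_cM, n_segments = n_segments)
  maha <- vapply(usable, function(env) {
    d <- c(sum_cM, n_segments) - env$mean
    cv <- env$cov + diag(1e-8 * (diag(env$cov) + 1), 2L)
    as.numeric(d %*% solve(cv, d))
  }, numeric(1))
  rel <- vapply(usable, function(e) e$relationship, character(1))
  ord <- order(ll, decreasing = TRUE)
  ranking <- data.frame(relationship = rel[ord], loglik = ll[ord],
                        mahalanobis2 = maha[ord], stringsAsFactors = FALSE)
  cutoff <- stats::qchisq(0.999, df = 2)
  if (all(maha > cutoff)) {
    call <- "unrelated/beyond 5th degree"
  } else {
    call <- ranking$relationship[ranking$loglik >= ranking$loglik[1L] - window]
  }
  list(call = call, ranking = ranking)
}
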