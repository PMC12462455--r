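#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorized.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range")
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Classify pairs into mortuary- versus geographic-proximity sets
#'
#' Implements the two pair definitions used to separate the effect of shared
#' mortuary tradition from plain geographic closeness:
#' * `mortuary_proximity` - same mortuary affiliation, sites further apart
#'   than `threshold_km` (different geographic areas), with at least one
#'   member from the focal region;
#' * `geographic_proximity` - different mortuary affiliations, sites within
#'   `threshold_km` of each other, both members from the focal region.
#' All other pairs are `excluded`. Whether two sites belong to the same
#' geographic area is decided by coordinates (great-circle distance
#' `<= threshold_km`, inclusive); region labels only select focal-region
#' membership.
#'
#' @param individuals Metadata data frame with columns `iid`, `group`
#'   (mortuary affiliation), `region`, `lat`, `lon`.
#' @param focal_region Region label of the focal contact zone.
#' @param threshold_km Same-area threshold (default 200 km, inclusive).
#' @return Data frame with one row per retained pair: `id_a`, `id_b`,
#'   `distance_km`, `same_mortuary`, `same_region`, `class`.
#' @export
classify_pairs <- function(individuals, focal_region, threshold_km = 200) {
  req <- c("iid", "group", "region", "lat", "lon")
  stopifnot(all(req %in% names(individuals)))
  miss <- is.na(individuals$lat) | is.na(individuals$lon)
  if (any(miss)) {
    warning("skipping individual(s) with missing coordinates: ",
            paste(individuals$iid[miss], collapse = ", "))
    individuals <- individuals[!miss, , drop = FALSE]
  }
  n <- nrow(individuals)
  if (n < 2L) stop("need at least two individuals with coordinates")
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  d <- haversine_km(individuals$lat[i], individuals$lon[i],
                    individuals$lat[j], individuals$lon[j])
  same_mort <- individuals$group[i] == individuals$group[j]
  same_reg <- d <= threshold_km
  focal_i <- individuals$region[i] == focal_region
  focal_j <- individuals$region[j] == focal_region
  cls <- rep("excluded", length(d))
  cls[same_mort & !same_reg & (focal_i | focal_j)] <- "mortuary_proximity"
  cls[!same_mort & same_reg & focal_i & focal_j] <- "geographic_proximity"
  a <- individuals$iid[i]; b <- individuals$iid[j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(id_a = a, id_b = b, distance_km = d,
             same_mortuary = same_mort, same_region = same_reg,
             class = cls, stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value via dynamic programming on doubled
# midranks (handles ties, unlike the exact branch of stats::wilcox.test).
# Counts, for each attainable sum s of m doubled midranks, the number of
# size-m subsets realizing it; p = 2 * min(P(W <= w), P(W >= w)) capped at 1.
rank_sum_exact_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r2 <- as.integer(round(2 * rank(c(x, y)))) # doubled midranks are integers
  w <- sum(r2[seq_len(m)])
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = m + 1L, ncol = max_sum + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- m
    for (k in kmax:1L) {
      shifted <- c(rep(0, v), counts[k, seq_len(max_sum + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[m + 1L, ]
  total <- sum(dist)
  p_le <- sum(dist[seq_len(w + 1L)]) / total
  p_ge <- sum(dist[(w + 1L):(max_sum + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

rank_sum_normal_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
  2 * stats::pnorm(-abs(z))
}

#' Two-sided Wilcoxon rank-sum comparison of two pair sets
#'
#' Compares per-pair IBD values (total or maximum segment length) between
#' two sets of pairs, e.g. the mortuary-proximity versus
#' geographic-proximity sets. Uses exact enumeration (tie-aware, by dynamic
#' programming) when both sets have at most `exact_max` values, otherwise
#' the tie- and continuity-corrected normal approximation.
#'
#' Pairs absent from `summaries` (no retained segment) enter with value 0
#' when `include_zero = TRUE` (default), so the pair universe is defined by
#' the labels, not by sharing.
#'
#' @param summaries Per-pair summaries from [summarize_pairs()].
#' @param pairs_a,pairs_b Data frames with columns `id_a`, `id_b` selecting
#'   the two pair sets (e.g. rows of [classify_pairs()] output).
#' @param measure `"sum"` or `"max"`.
#' @param include_zero Include pairs with no retained IBD as zeros.
#' @param exact_max Exact mode when both set sizes are `<= exact_max`.
#' @return List with `p`, `method`, per-set values (`values_a`,
#'   `values_b`) and descriptive statistics (`median_a`, `median_b`).
#' @export
compare_pair_sets <- function(summaries, pairs_a, pairs_b,
                              measure = c("sum", "max"),
                              include_zero = TRUE, exact_max = 12) {
  measure <- match.arg(measure)
  col <- if (measure == "sum") "sum_cM" else "max_cM"
  lookup <- function(pairs) {
    if (!nrow(pairs)) stop("empty pair set")
    key <- paste(pmin(pairs$id_a, pairs$id_b),
                 pmax(pairs$id_a, pairs$id_b), sep = "\r")
    skey <- paste(summaries$id_a, summaries$id_b, sep = "\r")
    v <- summaries[[col]][match(key, skey)]
    v[is.na(v)] <- 0
    if (!include_zero) v <- v[v > 0]
    v
  }
  a <- lookup(pairs_a)
  b <- lookup(pairs_b)
  if (!length(a) || !length(b)) stop("empty pair set after zero removal")
  if (length(a) <= exact_max && length(b) <= exact_max) {
    p <- rank_sum_exact_p(a, b)
    method <- "exact"
  } else {
    p <- rank_sum_normal_p(a, b)
    method <- "normal-approx"
  }
  list(p = p, method = method, measure = measure,
       values_a = a, values_b = b,
       median_a = stats::median(a), median_b = stats::median(b))
}
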