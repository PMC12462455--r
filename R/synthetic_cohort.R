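#' @title Synthetic cohorts
#' @description
#' Generates cohorts (individual metadata, IBD segment tables and
#' pseudo-haploid genotype matrices) with the statistical structure the
#' IBD-sharing analyses assume, so that every pipeline stage runs without
#' external data. Per-pair retained-segment counts are Poisson with a
#' group-pair intensity matrix `lambda`; segment lengths follow a shifted
#' exponential above the retention floor (`min_len + Exp(mean_excess)`);
#' chromosomes are drawn proportionally to map length and positions
#' uniformly within the chromosome. Optionally, specific pairs are
#' "planted" as true pedigree relatives: their segments come from the
#' pedigree simulator and their genotypes share alleles at the rate implied
#' by the kinship coefficient.
#' @name synthetic-cohort
NULL

#' Define a cohort scenario
#'
#' @param groups Data frame with columns `label`, `region`, `size`, `lat`,
#'   `lon` (one row per group; all members of a group share the site
#'   coordinates).
#' @param lambda Symmetric numeric matrix of expected retained-segment
#'   counts per pair, with group labels as dimnames.
#' @param min_len_cM Segment-length floor (cM).
#' @param mean_excess_cM Mean of the exponential length excess above the
#'   floor (cM).
#' @param snp_density_per_cM SNP density assigned to generated segments.
#' @param n_sites Number of panel sites for the genotype matrix.
#' @param beta_shape1,beta_shape2 Beta parameters of the allele-frequency
#'   spectrum.
#' @param missing_rate Per-site genotype missingness.
#' @param relatedness_plants Optional data frame with columns `id_a`,
#'   `id_b`, `relationship` naming pairs to embed as true pedigree
#'   relatives.
#' @return A `cohort_scenario` object.
#' @export
cohort_scenario <- function(groups, lambda, min_len_cM = 12,
                            mean_excess_cM = 8, snp_density_per_cM = 300,
                            n_sites = 10000, beta_shape1 = 0.8,
                            beta_shape2 = 0.8, missing_rate = 0,
                            relatedness_plants = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("label", "region", "size", "lat", "lon") %in% names(groups)),
            all(groups$size >= 1), mean_excess_cM > 0)
  lambda <- as.matrix(lambda)
  if (is.null(dimnames(lambda))) {
    dimnames(lambda) <- list(groups$label, groups$label)
  }
  if (!identical(sort(rownames(lambda)), sort(groups$label))) {
    stop("lambda dimnames must match group labels")
  }
  lambda <- lambda[groups$label, groups$label, drop = FALSE]
  if (any(lambda < 0)) stop("lambda entries must be >= 0")
  if (any(abs(lambda - t(lambda)) > 1e-12)) stop("lambda must be symmetric")
  structure(list(groups = groups, lambda = lambda, min_len_cM = min_len_cM,
                 mean_excess_cM = mean_excess_cM,
                 snp_density_per_cM = snp_density_per_cM,
                 n_sites = n_sites, beta_shape1 = beta_shape1,
                 beta_shape2 = beta_shape2, missing_rate = missing_rate,
                 relatedness_plants = relatedness_plants),
            class = "cohort_scenario")
}

#' Scenario presets for the replacement-versus-continuity analyses
#'
#' * `coexistence`: two sympatric groups (sizes 11 and 15 at one central
#'   site) with within-group intensity 2 and between-group intensity 0.5
#'   segments per pair - the label-shuffle test should reject.
#' * `replacement`: the four-group design (Fc n=3, Fe n=8, Sc n=6, So n=9)
#'   with source-successor sharing independent of the source region - the
#'   continuity test should behave as a null.
#' * `continuity`: as `replacement` but with the Fc-Sc intensity raised
#'   threefold - the continuity test should reject.
#'
#' @param name Preset name.
#' @return A `cohort_scenario`.
#' @export
cohort_preset <- function(name = c("coexistence", "replacement",
                                   "continuity")) {
  name <- match.arg(name)
  central <- c(47.4, 102.8)  # Orkhon valley
  eastern <- c(46.7, 111.9)
  northern <- c(49.3, 106.8) # outside-central successor sites
  base <- 0.5
  within <- 2
  if (name == "coexistence") {
    groups <- data.frame(
      label = c("F", "S"), region = c("central", "central"),
      size = c(11L, 15L), lat = central[1], lon = central[2],
      stringsAsFactors = FALSE
    )
    lam <- matrix(c(within, base, base, within), 2, 2,
                  dimnames = list(groups$label, groups$label))
    return(cohort_scenario(groups, lam))
  }
  groups <- data.frame(
    label = c("Fc", "Fe", "Sc", "So"),
    region = c("central", "eastern", "central", "northern"),
    size = c(3L, 8L, 6L, 9L),
    lat = c(central[1], eastern[1], central[1], northern[1]),
    lon = c(central[2], eastern[2], central[2], northern[2]),
    stringsAsFactors = FALSE
  )
  lam <- matrix(base, 4, 4, dimnames = list(groups$label, groups$label))
  diag(lam) <- within
  lam["Fc", "Fe"] <- lam["Fe", "Fc"] <- within # same source tradition
  lam["Sc", "So"] <- lam["So", "Sc"] <- within # same successor tradition
  if (name == "continuity") {
    lam["Fc", "Sc"] <- lam["Sc", "Fc"] <- 3 * base
  }
  cohort_scenario(groups, lam)
}

plant_degree <- function(relationship) {
  tab <- relationship_table()
  tab$degree[match(relationship, tab$relationship)]
}

#' Generate a synthetic cohort
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Optional integer seed; the whole cohort (segments and
#'   genotypes) is reproducible under a fixed seed.
#' @param map Genetic map used for chromosome assignment and planted
#'   relatives.
#' @return List with `meta` (metadata table), `segments` (segment table),
#'   `genotypes` (sites x individuals matrix of 0/1/9) and `matrix`
#'   (the pairwise total-IBD matrix of the generated segments).
#' @export
generate_cohort <- function(scenario, seed = NULL,
                            map = default_genetic_map()) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  if (!is.null(seed)) set.seed(seed)
  g <- scenario$groups
  ids <- unlist(lapply(seq_len(nrow(g)), function(i) {
    sprintf("%s%02d", g$label[i], seq_len(g$size[i]))
  }))
  grp_of <- rep(g$label, g$size)
  meta <- data.frame(
    iid = ids, group = grp_of,
    region = rep(g$region, g$size),
    lat = rep(g$lat, g$size), lon = rep(g$lon, g$size),
    date_lo = NA_integer_, date_hi = NA_integer_,
    sex = sample(c("F", "M"), length(ids), replace = TRUE),
    stringsAsFactors = FALSE
  )
  plants <- scenario$relatedness_plants
  planted_key <- character(0)
  if (!is.null(plants) && nrow(plants)) {
    if (length(setdiff(c(plants$id_a, plants$id_b), ids))) {
      stop("relatedness plant references unknown individual id")
    }
    planted_key <- paste(pmin(plants$id_a, plants$id_b),
                         pmax(plants$id_a, plants$id_b), sep = "\r")
  }
  chrom_prob <- map$length_cM / sum(map$length_cM)
  idx <- utils::combn(length(ids), 2L)
  seg_list <- vector("list", ncol(idx))
  for (p in seq_len(ncol(idx))) {
    i <- idx[1L, p]; j <- idx[2L, p]
    key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]), sep = "\r")
    if (key %in% planted_key) next # handled below
    lam <- scenario$lambda[grp_of[i], grp_of[j]]
    k <- if (lam > 0) stats::rpois(1L, lam) else 0L
    if (k == 0L) next
    len <- scenario$min_len_cM + stats::rexp(k, 1 / scenario$mean_excess_cM)
    ch <- sample(map$chrom, k, replace = TRUE, prob = chrom_prob)
    chlen <- map$length_cM[match(ch, map$chrom)]
    len <- pmin(len, chlen) # never longer than the chromosome
    start <- stats::runif(k, 0, chlen - len)
    seg_list[[p]] <- data.frame(
      id_a = ids[i], id_b = ids[j], chrom = ch,
      start_cM = start, end_cM = start + len, length_cM = len,
      n_snps = as.integer(round(len * scenario$snp_density_per_cM)),
      state = "IBD1", stringsAsFactors = FALSE
    )
  }
  if (length(planted_key)) {
    for (q in seq_len(nrow(plants))) {
      reps <- simulate_relationship(plants$relationship[q], n_rep = 1,
                                    map = map,
                                    snp_density_per_cM =
                                      scenario$snp_density_per_cM,
                                    merge = TRUE, filter = TRUE,
                                    min_len_cM = scenario$min_len_cM,
                                    min_density = 0)
      d <- reps[[1L]]
      if (nrow(d)) {
        d$id_a <- min(plants$id_a[q], plants$id_b[q])
        d$id_b <- max(plants$id_a[q], plants$id_b[q])
        seg_list[[length(seg_list) + 1L]] <- d
      }
    }
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) {
    segments <- data.frame(id_a = character(), id_b = character(),
                           chrom = integer(), start_cM = numeric(),
                           end_cM = numeric(), length_cM = numeric(),
                           n_snps = integer(), state = character(),
                           stringsAsFactors = FALSE)
  } else {
    segments <- validate_segments(segments)
  }
  # pseudo-haploid genotypes: Beta-distributed allele frequencies, one
  # sampled allele per site; planted relatives copy alleles at the rate of
  # their kinship coefficient
  n_sites <- scenario$n_sites
  freqs <- stats::rbeta(n_sites, scenario$beta_shape1, scenario$beta_shape2)
  genos <- matrix(9L, nrow = n_sites, ncol = length(ids),
                  dimnames = list(NULL, ids))
  for (c_i in seq_along(ids)) {
    genos[, c_i] <- as.integer(stats::runif(n_sites) < freqs)
  }
  if (length(planted_key)) {
    for (q in seq_len(nrow(plants))) {
      phi <- 2^-(plant_degree(plants$relationship[q]) + 1L)
      copy <- stats::runif(n_sites) < phi
      genos[copy, plants$id_b[q]] <- genos[copy, plants$id_a[q]]
    }
  }
  if (scenario$missing_rate > 0) {
    drop <- matrix(stats::runif(length(genos)) < scenario$missing_rate,
                   nrow = n_sites)
    genos[drop] <- 9L
  }
  list(meta = meta, segments = segments, genotypes = genos,
       matrix = build_ibd_matrix(summarize_pairs(segments), ids))
}

#' Write a generated cohort to the three standard tables
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed). Writes `meta.tsv`,
#'   `segments.tsv`, `genotypes.tsv` and `matrix.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ibd_segments(cohort$segments, file.path(dir, "segments.tsv"))
  utils::write.table(cohort$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ibd_matrix(cohort$matrix, file.path(dir, "matrix.csv"))
  invisible(dir)
}
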