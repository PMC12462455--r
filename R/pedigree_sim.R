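#' @title Pedigree IBD simulation
#' @description
#' A gene-dropping simulator for the IBD segments shared by a pair of
#' individuals in a known pedigree relationship. Founder chromosomes carry
#' unique labels; each meiosis lays crossovers down the genetic map
#' according to a stationary gamma-renewal process (shape `nu`; `nu = 1`
#' gives a Poisson process with one crossover per Morgan, `nu > 1` models
#' positive crossover interference) and transmits an alternating mosaic of
#' the parent's two haplotypes. IBD1/IBD2 states of the focal pair are read
#' off by overlaying the four haplotype label mosaics. Simulated segments
#' can then be state-merged and filtered exactly like called segments,
#' yielding the per-relationship (total cM, segment count) envelopes used
#' for degree classification.
#'
#' Founders that appear only once in a pedigree contribute a single fresh
#' founder label instead of an explicit meiosis - IBD-equivalent, since
#' their material can never match anything else.
#' @name pedigree-sim
NULL

#' The 14 supported pedigree relationships
#'
#' @return Data frame with columns `relationship`, `degree` (relationship
#'   degree), `n_meioses` (meioses separating the pair) and `expected_any`
#'   (expected fraction of the genome in IBD1 or IBD2), ordered by
#'   decreasing expected sharing.
#' @export
relationship_table <- function() {
  df <- data.frame(
    relationship = c("Parent-Child", "Siblings",
                     "Grandparent-Grandchild", "Avuncular", "Half-Siblings",
                     "Double-Cousins",
                     "First-Cousins", "Great-Grandparent",
                     "Half-First-Cousins", "Great-Great-Grandparent",
                     "Second-Cousins", "Third-Great-Grandparent",
                     "Half-Second-Cousins", "Third-Cousins"),
    degree = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 7L),
    n_meioses = c(1L, 2L, 2L, 3L, 2L, 4L, 4L, 3L, 4L, 4L, 6L, 5L, 6L, 8L),
    expected_any = c(1, 0.75, 0.5, 0.5, 0.5, 7 / 16, 0.25, 0.25,
                     0.125, 0.125, 0.0625, 0.0625, 0.03125, 0.015625),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname relationship_table
#' @export
relationship_labels <- function() relationship_table()$relationship

# Crossover positions on a chromosome of length L cM, stationary
# gamma-renewal with shape nu and mean inter-crossover distance 100 cM.
# nu = 1 is an exact homogeneous Poisson process; otherwise the renewal
# process is burnt in over 10 Morgans before the chromosome start.
crossover_points <- function(L, nu = 1) {
  if (L <= 0) return(numeric(0))
  if (nu == 1) {
    n <- stats::rpois(1L, L / 100)
    if (n == 0L) return(numeric(0))
    return(sort.int(stats::runif(n, 0, L)))
  }
  burn <- 1000
  total <- L + burn
  n_guess <- ceiling(total / 100 + 4 * sqrt(total / 100 / nu) + 10)
  pos <- cumsum(stats::rgamma(n_guess, shape = nu, rate = nu / 100))
  while (pos[length(pos)] < total) {
    pos <- c(pos, pos[length(pos)] +
               cumsum(stats::rgamma(n_guess, shape = nu, rate = nu / 100)))
  }
  pos <- pos - burn
  pos[pos > 0 & pos < L]
}

#' Simulate one meiosis across the genetic map
#'
#' @param map Genetic map data frame (see [default_genetic_map()]).
#' @param interference_nu Gamma-renewal shape; 1 = Poisson (no
#'   interference), larger values give underdispersed crossover counts.
#' @param seed Optional integer seed.
#' @return Named list of crossover position vectors (cM), one per
#'   chromosome.
#' @export
simulate_meiosis <- function(map = default_genetic_map(),
                             interference_nu = 1, seed = NULL) {
  validate_genetic_map(map)
  stopifnot(interference_nu > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(map$length_cM, crossover_points, nu = interference_nu)
  names(out) <- as.character(map$chrom)
  out
}

# A haplotype is list(bp = breakpoints c(0, ..., L), lab = founder labels,
# one per interval). A recombination product of the parent's two haplotypes:
gamete_hap <- function(parent, L, nu) {
  xo <- crossover_points(L, nu)
  phase <- sample.int(2L, 1L)
  if (!length(xo)) return(parent[[phase]])
  bounds <- c(0, xo, L)
  starts <- NULL
  labs <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    h <- parent[[((phase - 1L + k - 1L) %% 2L) + 1L]]
    from <- bounds[k]; to <- bounds[k + 1L]
    i <- findInterval(from, h$bp)
    j <- findInterval(to, h$bp, left.open = TRUE)
    starts <- c(starts, from, if (j > i) h$bp[(i + 1L):j])
    labs <- c(labs, h$lab[i:j])
  }
  keep <- c(TRUE, labs[-1L] != labs[-length(labs)])
  list(bp = c(starts[keep], L), lab = labs[keep])
}

# Per-chromosome pedigree drop for one relationship; returns the two focal
# individuals, each a list of two haplotypes.
drop_pair <- function(relationship, L, nu) {
  cnt <- 0L
  fresh <- function() { cnt <<- cnt + 1L; list(bp = c(0, L), lab = cnt) }
  founder <- function() list(fresh(), fresh())
  gam <- function(ind) gamete_hap(ind, L, nu)
  child <- function(p, m) list(gam(p), gam(m))
  childF <- function(p) list(gam(p), fresh()) # other parent terminal founder
  lineal <- function(anc, n_down) {
    x <- childF(anc)
    for (i in seq_len(n_down - 1L)) x <- childF(x)
    x
  }
  switch(relationship,
    "Parent-Child" = {
      p <- founder(); list(p, childF(p))
    },
    "Siblings" = {
      f <- founder(); m <- founder(); list(child(f, m), child(f, m))
    },
    "Grandparent-Grandchild" = {
      g <- founder(); list(g, lineal(g, 2L))
    },
    "Avuncular" = {
      f <- founder(); m <- founder()
      a <- child(f, m); b <- child(f, m)
      list(a, childF(b))
    },
    "Half-Siblings" = {
      p <- founder(); list(childF(p), childF(p))
    },
    "Double-Cousins" = {
      f1 <- founder(); m1 <- founder(); f2 <- founder(); m2 <- founder()
      a1 <- child(f1, m1); a2 <- child(f1, m1)
      b1 <- child(f2, m2); b2 <- child(f2, m2)
      list(child(a1, b1), child(a2, b2))
    },
    "First-Cousins" = {
      f <- founder(); m <- founder()
      list(childF(child(f, m)), childF(child(f, m)))
    },
    "Second-Cousins" = {
      f <- founder(); m <- founder()
      list(lineal(child(f, m), 2L), lineal(child(f, m), 2L))
    },
    "Third-Cousins" = {
      f <- founder(); m <- founder()
      list(lineal(child(f, m), 3L), lineal(child(f, m), 3L))
    },
    "Half-First-Cousins" = {
      p <- founder()
      list(childF(childF(p)), childF(childF(p)))
    },
    "Half-Second-Cousins" = {
      p <- founder()
      list(lineal(childF(p), 2L), lineal(childF(p), 2L))
    },
    "Great-Grandparent" = {
      g <- founder(); list(g, lineal(g, 3L))
    },
    "Great-Great-Grandparent" = {
      g <- founder(); list(g, lineal(g, 4L))
    },
    "Third-Great-Grandparent" = {
      g <- founder(); list(g, lineal(g, 5L))
    },
    stop("unknown relationship '", relationship, "'; expected one of: ",
         paste(relationship_labels(), collapse = ", "))
  )
}

# Overlay the four haplotypes of a pair; returns runs of constant IBD state
# (> 0) as list(start, end, state) with state 1 = IBD1, 2 = IBD2.
pair_ibd_runs <- function(a, b) {
  bp <- sort(unique(c(a[[1L]]$bp, a[[2L]]$bp, b[[1L]]$bp, b[[2L]]$bp)))
  n <- length(bp) - 1L
  mid <- (bp[-1L] + bp[-(n + 1L)]) / 2
  a1 <- a[[1L]]$lab[findInterval(mid, a[[1L]]$bp)]
  a2 <- a[[2L]]$lab[findInterval(mid, a[[2L]]$bp)]
  b1 <- b[[1L]]$lab[findInterval(mid, b[[1L]]$bp)]
  b2 <- b[[2L]]$lab[findInterval(mid, b[[2L]]$bp)]
  ibd2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
  any1 <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
  state <- ifelse(ibd2, 2L, ifelse(any1, 1L, 0L))
  r <- rle(state)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values > 0L
  list(start = bp[starts_idx[keep]], end = bp[ends_idx[keep] + 1L],
       state = r$values[keep])
}

#' Simulate IBD segments for a pedigree relationship
#'
#' Gene-drops `n_rep` independent replicates of the minimal pedigree
#' connecting the pair and reports their shared IBD segments per autosome.
#' With `merge = TRUE`, abutting IBD1/IBD2 state runs are merged into single
#' blocks (the convention of haplotype-based IBD callers, which do not
#' separate the two states); with `filter = TRUE` the merged blocks are then
#' passed through the standard length/density filter. SNP counts are
#' assigned as `round(length_cM * snp_density_per_cM)`, so with the default
#' density of 300/cM the 220 SNPs-per-cM filter is effectively length-driven.
#'
#' @param relationship One of [relationship_labels()].
#' @param n_rep Number of replicates (default 100).
#' @param map Genetic map (default [default_genetic_map()]).
#' @param interference_nu Crossover interference shape (1 = Poisson).
#' @param snp_density_per_cM SNP density assigned to simulated segments.
#' @param seed Optional integer seed.
#' @param merge Merge adjacent IBD1/IBD2 runs.
#' @param filter Apply [filter_segments()] thresholds after merging.
#' @param min_len_cM,min_density Filter thresholds.
#' @return List of `n_rep` segment tables (see [ibd-segments]) with ids
#'   `"simA"`/`"simB"`; replicates with no segments are 0-row tables.
#' @export
simulate_relationship <- function(relationship, n_rep = 100,
                                  map = default_genetic_map(),
                                  interference_nu = 1,
                                  snp_density_per_cM = 300,
                                  seed = NULL, merge = TRUE, filter = TRUE,
                                  min_len_cM = 12, min_density = 220) {
  if (!relationship %in% relationship_labels()) {
    stop("unknown relationship '", relationship, "'; expected one of: ",
         paste(relationship_labels(), collapse = ", "))
  }
  validate_genetic_map(map)
  stopifnot(n_rep >= 1, interference_nu > 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_rep), function(rep_i) {
    chrom <- integer(0); start <- numeric(0); end <- numeric(0)
    state <- integer(0)
    for (ci in seq_len(nrow(map))) {
      pr <- drop_pair(relationship, map$length_cM[ci], interference_nu)
      runs <- pair_ibd_runs(pr[[1L]], pr[[2L]])
      if (length(runs$state)) {
        chrom <- c(chrom, rep(map$chrom[ci], length(runs$state)))
        start <- c(start, runs$start)
        end <- c(end, runs$end)
        state <- c(state, runs$state)
      }
    }
    if (merge && length(state) > 1L) {
      # abutting state runs on the same chromosome collapse into one block
      new_block <- c(TRUE, !(chrom[-1L] == chrom[-length(chrom)] &
                               start[-1L] <= end[-length(end)] + 1e-12))
      grp <- factor(cumsum(new_block), levels = unique(cumsum(new_block)))
      chrom2 <- chrom[new_block]
      start2 <- tapply(start, grp, min)
      end2 <- tapply(end, grp, max)
      state2 <- as.integer(tapply(state, grp, min)) # any IBD1 -> IBD1
      chrom <- chrom2; start <- as.numeric(start2); end <- as.numeric(end2)
      state <- state2
    }
    df <- data.frame(
      id_a = rep("simA", length(state)), id_b = rep("simB", length(state)),
      chrom = chrom, start_cM = start, end_cM = end,
      length_cM = end - start,
      n_snps = as.integer(round((end - start) * snp_density_per_cM)),
      state = c("IBD1", "IBD2")[state],
      stringsAsFactors = FALSE
    )
    if (filter && nrow(df)) {
      df <- filter_segments(df, min_len_cM = min_len_cM,
                            min_density = min_density)
    }
    df
  })
}

#' Per-replicate (sum, count) points of a simulated relationship
#'
#' @param replicates List of segment tables from [simulate_relationship()].
#' @return Data frame with `sum_cM` and `n_segments`, one row per replicate
#'   (zeros for replicates with no segments).
#' @export
envelope_points <- function(replicates) {
  data.frame(
    sum_cM = vapply(replicates, function(d) sum(d$length_cM), numeric(1)),
    n_segments = vapply(replicates, nrow, integer(1))
  )
}

#' Build relationship envelopes for degree classification
#'
#' Simulates each requested relationship, merges and filters the segments,
#' and fits a bivariate-normal envelope on the per-replicate
#' (total cM, segment count) points. Reproducible under a fixed seed.
#'
#' @inheritParams simulate_relationship
#' @param relationships Character vector of relationship labels (default:
#'   all 14).
#' @return Named list of [fit_envelope()] objects.
#' @export
build_envelopes <- function(relationships = relationship_labels(),
                            n_rep = 100, map = default_genetic_map(),
                            interference_nu = 1, snp_density_per_cM = 300,
                            seed = NULL, min_len_cM = 12, min_density = 220) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(relationships, function(rel) {
    reps <- simulate_relationship(rel, n_rep = n_rep, map = map,
                                  interference_nu = interference_nu,
                                  snp_density_per_cM = snp_density_per_cM,
                                  seed = NULL, merge = TRUE, filter = TRUE,
                                  min_len_cM = min_len_cM,
                                  min_density = min_density)
    fit_envelope(rel, envelope_points(reps))
  })
  names(out) <- relationships
  out
}
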