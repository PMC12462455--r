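# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (explicit double loops) so it cannot share a bug with
# the vectorized implementations it checks.

random_ibd_matrix <- function(n, zero_prob = 0.4) {
  m <- matrix(0, n, n, dimnames = list(paste0("I", seq_len(n)),
                                       paste0("I", seq_len(n))))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (runif(1) < zero_prob) 0 else round(rexp(1, 1 / 15), 3)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

bf_mean_pair <- function(m, a, b = NULL) {
  if (is.null(b) || setequal(a, b)) {
    tot <- 0; np <- 0
    for (i in seq_along(a)) {
      for (j in seq_along(a)) {
        if (i < j) { tot <- tot + m[a[i], a[j]]; np <- np + 1 }
      }
    }
  } else {
    tot <- 0; np <- 0
    for (x in a) for (y in b) { tot <- tot + m[x, y]; np <- np + 1 }
  }
  tot / np
}

bf_within_between <- function(m, labels) {
  gs <- split(names(labels), as.character(labels))
  (bf_mean_pair(m, gs[[1]]) + bf_mean_pair(m, gs[[2]])) / 2 -
    bf_mean_pair(m, gs[[1]], gs[[2]])
}

bf_continuity_stat <- function(fs, fc, sc, zero_sub = 0.01) {
  fe <- setdiff(rownames(fs), fc)
  so <- setdiff(colnames(fs), sc)
  avg <- function(r, c) {
    tot <- 0
    for (x in r) for (y in c) tot <- tot + fs[x, y]
    tot / (length(r) * length(c))
  }
  fcso <- avg(fc, so); if (fcso == 0) fcso <- zero_sub
  feso <- avg(fe, so); if (feso == 0) feso <- zero_sub
  denom <- avg(fe, sc) / feso
  if (denom == 0) denom <- zero_sub
  (avg(fc, sc) / fcso) / denom
}

bf_contribution_stat <- function(fs, fc, zero_sub = 0.01) {
  fe <- setdiff(rownames(fs), fc)
  avg <- function(r) {
    tot <- 0
    for (x in r) for (y in colnames(fs)) tot <- tot + fs[x, y]
    tot / (length(r) * ncol(fs))
  }
  fcs <- avg(fc)
  if (fcs == 0) fcs <- zero_sub
  avg(fe) / fcs
}

# exact two-sided rank-sum p by complete subset enumeration (tiny n only)
bf_rank_sum_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  ws <- combn(N, m, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w)
  p_ge <- mean(ws >= w)
  min(1, 2 * min(p_le, p_ge))
}

# segment row constructor
seg_row <- function(id_a, id_b, chrom, start, end, n_snps = NULL,
                    state = "IBD1") {
  if (is.null(n_snps)) n_snps <- as.integer(round((end - start) * 300))
  data.frame(id_a = id_a, id_b = id_b, chrom = chrom, start_cM = start,
             end_cM = end, length_cM = end - start, n_snps = n_snps,
             state = state, stringsAsFactors = FALSE)
}

two_group_labels <- function(m, n1) {
  ids <- rownames(m)
  stats::setNames(rep(c("G1", "G2"), c(n1, length(ids) - n1)), ids)
}
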