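test_that("label shuffle on a constant matrix is degenerate", {
  m <- matrix(2, 8, 8, dimnames = list(paste0("I", 1:8), paste0("I", 1:8)))
  diag(m) <- 0
  r <- label_shuffle_test(m, two_group_labels(m, 4), n_perm = 50, seed = 1)
  expect_equal(r$observed, 0, tolerance = 1e-12)
  expect_true(all(abs(r$null) < 1e-12))
  expect_equal(r$p, 1)
})

test_that("permutation results are reproducible and well-formed", {
  set.seed(42)
  m <- random_ibd_matrix(10)
  labs <- two_group_labels(m, 4)
  r1 <- label_shuffle_test(m, labs, n_perm = 300, seed = 99)
  r2 <- label_shuffle_test(m, labs, n_perm = 300, seed = 99)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$n_perm, 300L)
  expect_equal(r1$p, empirical_p(r1$null, r1$observed))
  # p is a multiple of 1/N
  expect_equal(r1$p * 300, round(r1$p * 300), tolerance = 1e-9)
  expect_error(label_shuffle_test(m, labs, n_perm = 0), "n_perm")
})

test_that("label shuffle null is centred near zero on a centred matrix", {
  set.seed(7)
  m <- random_ibd_matrix(12, zero_prob = 0)
  off <- m[upper.tri(m)]
  m[upper.tri(m)] <- off - mean(off)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m <- m - min(m); diag(m) <- 0 # keep entries >= 0 after centring
  r <- label_shuffle_test(m, two_group_labels(m, 6), n_perm = 2000, seed = 4)
  expect_lt(abs(mean(r$null)), 3 * sd(r$null) / sqrt(2000))
})

test_that("continuity test is degenerate under identical columns", {
  fs <- matrix(rep(c(4, 1, 0, 2.5, 7), 6), nrow = 5,
               dimnames = list(paste0("F", 1:5), paste0("S", 1:6)))
  r <- continuity_test(fs, fc_rows = c("F1", "F2"), sc_cols = c("S1", "S2"),
                       n_perm = 100, seed = 3)
  expect_true(all(abs(r$null - r$observed) < 1e-12))
  expect_equal(r$p, 1)
})

test_that("continuity test statistic matches the brute-force oracle", {
  set.seed(11)
  for (i in 1:20) {
    fs <- matrix(round(rexp(30, 1 / 5), 2) *
                   rbinom(30, 1, 0.6), nrow = 5,
                 dimnames = list(paste0("F", 1:5), paste0("S", 1:6)))
    fc <- paste0("F", 1:2); sc <- paste0("S", 1:3)
    r <- continuity_test(fs, fc, sc, n_perm = 1, seed = 1)
    expect_equal(r$observed, bf_continuity_stat(fs, fc, sc),
                 tolerance = 1e-12)
  }
  expect_error(continuity_test(fs, paste0("F", 1:2), paste0("S", 1:6)),
               "Sc size")
})

test_that("contribution test enumerates the exact null", {
  set.seed(13)
  fs <- matrix(round(rexp(12, 1 / 4), 2), nrow = 4,
               dimnames = list(paste0("F", 1:4), paste0("S", 1:3)))
  r <- contribution_test(fs, fc_rows = c("F1", "F3"), mode = "exhaustive")
  expect_equal(r$n_perm, choose(4, 2))
  expect_identical(r$seed, "exhaustive")
  # brute-force enumeration over all C(4,2) row assignments
  combos <- combn(paste0("F", 1:4), 2)
  bf_null <- apply(combos, 2, function(fc) bf_contribution_stat(fs, fc))
  expect_equal(sort(r$null), sort(bf_null), tolerance = 1e-12)
  expect_equal(r$observed, bf_contribution_stat(fs, c("F1", "F3")),
               tolerance = 1e-12)

  # exhaustive mode is seed-independent (seed never consulted)
  r2 <- contribution_test(fs, fc_rows = c("F1", "F3"), mode = "exhaustive")
  expect_identical(r$null, r2$null)
})

test_that("the paper-scale design yields 165 exhaustive assignments", {
  set.seed(17)
  fs <- matrix(rexp(11 * 15, 1 / 2) * rbinom(11 * 15, 1, 0.3), nrow = 11,
               dimnames = list(paste0("F", 1:11), paste0("S", 1:15)))
  r <- contribution_test(fs, fc_rows = paste0("F", 1:3), mode = "exhaustive")
  expect_equal(r$n_perm, 165L)
  expect_equal(length(r$null), 165L)
})

test_that("zero denominators are substituted, flagged and retained", {
  # Fc rows all zero: FcS = 0 -> substituted with 0.01
  fs <- matrix(0, nrow = 4, ncol = 3,
               dimnames = list(paste0("F", 1:4), paste0("S", 1:3)))
  fs["F3", ] <- 2
  fs["F4", ] <- 2
  r <- contribution_test(fs, fc_rows = c("F1", "F2"), mode = "exhaustive")
  expect_equal(r$observed, 2 / 0.01, tolerance = 1e-12)
  expect_gt(r$n_substituted, 0)
  expect_equal(r$n_perm, 6L) # substituted permutations stay in the count
  expect_true(length(r$extreme) >= 1) # flagged as extreme, not dropped
  # refusing oversized exhaustive enumeration
  big <- matrix(1, 30, 3, dimnames = list(paste0("F", 1:30), paste0("S", 1:3)))
  expect_error(contribution_test(big, paste0("F", 1:15), mode = "exhaustive",
                                 max_exhaustive = 1e4), "sampled")
})

test_that("sampled contribution mode is seeded and sized", {
  fs <- matrix(rexp(12), nrow = 4,
               dimnames = list(paste0("F", 1:4), paste0("S", 1:3)))
  r1 <- contribution_test(fs, "F1", mode = "sampled", n_perm = 50, seed = 5)
  r2 <- contribution_test(fs, "F1", mode = "sampled", n_perm = 50, seed = 5)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$n_perm, 50L)
})
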