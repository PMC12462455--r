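test_that("haversine distance matches closed forms", {
  expect_equal(haversine_km(47, 102, 47, 102), 0)
  # one degree of meridian arc at R = 6371
  expect_equal(haversine_km(47, 102, 48, 102), 6371 * pi / 180,
               tolerance = 1e-9)
  # antipodal points
  expect_equal(haversine_km(10, 20, -10, -160), pi * 6371, tolerance = 1e-6)
  expect_error(haversine_km(91, 0, 0, 0), "out of range")
  expect_error(haversine_km(0, 181, 0, 0), "out of range")
})

test_that("pair classification implements the 2x2 definition table", {
  # sites: two central (same place), one 'north' ~360 km away, one far east
  inds <- data.frame(
    iid = c("C_dskc1", "C_dskc2", "C_fig1", "N_dskc", "E_fig"),
    group = c("DSKC", "DSKC", "Figure", "DSKC", "Figure"),
    region = c("central", "central", "central", "north", "east"),
    lat = c(47.4, 47.4, 47.4, 50.6, 46.7),
    lon = c(102.8, 102.8, 102.8, 103.5, 111.9),
    stringsAsFactors = FALSE
  )
  pc <- classify_pairs(inds, focal_region = "central", threshold_km = 200)
  key <- paste(pc$id_a, pc$id_b)
  cls <- setNames(pc$class, key)
  # same mortuary, ~360 km apart, one member focal -> mortuary proximity
  expect_equal(unname(cls["C_dskc1 N_dskc"]), "mortuary_proximity")
  # different mortuary, same site, both focal -> geographic proximity
  expect_equal(unname(cls["C_dskc1 C_fig1"]), "geographic_proximity")
  # same mortuary, same region -> excluded
  expect_equal(unname(cls["C_dskc1 C_dskc2"]), "excluded")
  # same mortuary, far apart, one focal member -> mortuary proximity
  expect_equal(unname(cls["C_fig1 E_fig"]), "mortuary_proximity")
  # different mortuary, far apart -> excluded
  expect_equal(unname(cls["C_dskc1 E_fig"]), "excluded")
  expect_gt(pc$distance_km[key == "C_dskc1 N_dskc"], 300)
})

test_that("classification is symmetric and monotone in the threshold", {
  set.seed(23)
  inds <- data.frame(
    iid = sprintf("I%02d", 1:12),
    group = sample(c("A", "B"), 12, replace = TRUE),
    region = sample(c("central", "out"), 12, replace = TRUE),
    lat = runif(12, 45, 50), lon = runif(12, 100, 110),
    stringsAsFactors = FALSE
  )
  pc1 <- classify_pairs(inds, "central")
  pc2 <- classify_pairs(inds[sample(12), ], "central")
  o <- function(d) d[order(d$id_a, d$id_b), c("id_a", "id_b", "class")]
  expect_equal(o(pc1), o(pc2), ignore_attr = TRUE)

  # raising the threshold only moves pairs mortuary->excluded and
  # excluded->geographic
  lo <- classify_pairs(inds, "central", threshold_km = 100)
  hi <- classify_pairs(inds, "central", threshold_km = 400)
  key <- paste(lo$id_a, lo$id_b)
  hi_cls <- setNames(hi$class, paste(hi$id_a, hi$id_b))[key]
  allowed <- list(
    mortuary_proximity = c("mortuary_proximity", "excluded"),
    geographic_proximity = c("geographic_proximity"),
    excluded = c("excluded", "geographic_proximity")
  )
  for (k in seq_along(key)) {
    expect_true(hi_cls[k] %in% allowed[[lo$class[k]]])
  }
})

test_that("exact rank-sum handles ties and matches enumeration", {
  # identical multisets -> p = 1 in exact mode
  s <- data.frame(id_a = character(), id_b = character(), sum_cM = numeric(),
                  max_cM = numeric(), n_segments = integer())
  pa <- data.frame(id_a = c("a", "b"), id_b = c("x", "y"))
  pb <- data.frame(id_a = c("c", "d"), id_b = c("x", "y"))
  r <- compare_pair_sets(s, pa, pb) # all values 0 -> full ties
  expect_equal(r$p, 1)
  expect_equal(r$method, "exact")

  # {1,2,3} vs {4,5,6}: 2 of 20 orderings
  expect_equal(paleoibd:::rank_sum_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)

  # random small multisets (with ties) against complete enumeration
  set.seed(31)
  for (i in 1:50) {
    x <- sample(0:4, sample(2:5, 1), replace = TRUE)
    y <- sample(0:4, sample(2:5, 1), replace = TRUE)
    expect_equal(paleoibd:::rank_sum_exact_p(x, y), bf_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree at n = 12", {
  set.seed(37)
  for (i in 1:50) {
    x <- rexp(12, 0.1); y <- rexp(12, 0.08) # continuous: tie-free
    pe <- paleoibd:::rank_sum_exact_p(x, y)
    pn <- paleoibd:::rank_sum_normal_p(x, y)
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("compare_pair_sets looks up pair values with zero inclusion", {
  segs <- rbind(seg_row("A", "X", 1, 0, 14), seg_row("A", "X", 2, 0, 20),
                seg_row("B", "Y", 1, 0, 40))
  s <- summarize_pairs(segs)
  pa <- data.frame(id_a = c("A", "B"), id_b = c("X", "Y"))
  pb <- data.frame(id_a = c("C", "D"), id_b = c("X", "Y")) # no sharing
  r_sum <- compare_pair_sets(s, pa, pb, measure = "sum")
  expect_equal(sort(r_sum$values_a), c(34, 40))
  expect_equal(r_sum$values_b, c(0, 0))
  r_max <- compare_pair_sets(s, pa, pb, measure = "max")
  expect_equal(sort(r_max$values_a), c(20, 40))
  # positive-only mode drops the zero pairs entirely
  expect_error(compare_pair_sets(s, pb, pa, include_zero = FALSE), "empty")
  # reversed id order finds the same pairs
  pa_rev <- data.frame(id_a = c("X", "Y"), id_b = c("A", "B"))
  r_rev <- compare_pair_sets(s, pa_rev, pb, measure = "sum")
  expect_equal(sort(r_rev$values_a), c(34, 40))
})
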