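test_that("rarefaction matches exhaustive subsample enumeration", {
  r <- rarefy_richness(c(3, 2, 1), 2)
  o <- oracle_rarefy(c(3, 2, 1), 2)
  expect_equal(r$expected, o$expected, tolerance = 1e-12)
  expect_equal(r$variance, o$variance, tolerance = 1e-12)
  # every composition with N <= 8, every subsample size
  comps <- list(c(1, 1), c(2, 1), c(4), c(2, 2, 1), c(3, 3),
                c(5, 1, 1), c(4, 2, 2), c(1, 1, 1, 1, 1, 1, 1, 1),
                c(6, 2), c(3, 2, 2, 1))
  for (cc in comps) {
    for (n in seq_len(sum(cc))) {
      r <- rarefy_richness(cc, n)
      o <- oracle_rarefy(cc, n)
      expect_equal(r$expected, o$expected, tolerance = 1e-10)
      expect_equal(r$variance, o$variance, tolerance = 1e-10)
    }
  }
})

test_that("rarefaction boundary behaviour and monotonicity hold", {
  counts <- c(10, 5, 3, 1, 1)
  N <- sum(counts)
  full <- rarefy_richness(counts, N)
  expect_equal(full$expected, 5)
  expect_equal(full$variance, 0)
  one <- rarefy_richness(counts, 1)
  expect_equal(one$expected, 1)
  expect_equal(one$variance, 0, tolerance = 1e-12)
  expect_error(rarefy_richness(counts, 0), "out of range")
  expect_error(rarefy_richness(counts, N + 1), "out of range")

  cur <- rarefaction_curve(counts, step = 1)
  expect_true(all(diff(cur$expected) >= -1e-12))
  expect_equal(cur$expected[nrow(cur)], 5)
  # single phylotype: flat at 1
  flat <- rarefaction_curve(c(7), step = 2)
  expect_true(all(abs(flat$expected - 1) < 1e-12))
  # curve points equal pointwise calls
  expect_equal(cur$expected[3], rarefy_richness(counts, 3)$expected)
})

test_that("expected richness agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  counts <- c(12, 7, 5, 3, 2, 1, 1)
  for (n in c(2, 5, 10, 20)) {
    ref <- vegan::rarefy(counts, n, se = TRUE)
    r <- rarefy_richness(counts, n)
    expect_equal(r$expected, unname(ref[1, ]), tolerance = 1e-8)
  }
})

test_that("sufficiency criterion evaluates the CI half-width", {
  counts <- c(20, 1, 1, 1, 1)  # dominant plus singletons
  chk <- sufficiency_check(counts, threshold = 0.01)
  expect_false(chk$sufficient)
  expect_true(sufficiency_check(counts, threshold = Inf)$sufficient)
  pen <- rarefy_richness(counts, sum(counts) - 1)
  expect_equal(chk$ci_halfwidth, 1.96 * sqrt(pen$variance))
  expect_equal(chk$at_n, sum(counts) - 1)
})

test_that("generality profiles summarize occupied-sample pH", {
  st <- sample_table(data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s1", "s2", "s3"),
    group = "g1",
    ph = c(4.0, 5.5, 7.4, 6.0, 4.0, 5.5, 7.4),
    phylotype = c("wide", "wide", "wide", "rare", "two", "two", "one")))
  prof <- generality_profiles(st)
  wide <- prof[prof$phylotype == "wide", ]
  expect_equal(wide$min_ph, 4.0)
  expect_equal(wide$sd_ph, sd(c(4.0, 5.5, 7.4)))
  expect_true(wide$included)
  expect_false(prof[prof$phylotype == "two", "included"])
  expect_true(is.na(prof[prof$phylotype == "one", "sd_ph"]))

  st_bad <- sample_table(data.frame(
    sample_id = c("s1", "s2", "s3"), group = "g", ph = c(4, NA, 5),
    phylotype = c("a", "a", "a")))
  expect_error(generality_profiles(st_bad), "s2")
})

test_that("generality correlation equals the textbook Pearson computation", {
  prof <- data.frame(
    phylotype = letters[1:6], n_samples_present = 5,
    min_ph = c(3.1, 3.8, 4.5, 5.2, 6.0, 6.6),
    sd_ph = c(1.4, 1.3, 0.9, 1.0, 0.5, 0.3),
    included = TRUE)
  res <- generality_correlation(prof)
  x <- prof$sd_ph
  y <- prof$min_ph
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_hand * sqrt((6 - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(tstat), df = 4)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$n, 6)
  expect_lt(res$r, 0)

  # perfectly collinear negative relationship
  prof$sd_ph <- 10 - prof$min_ph
  expect_equal(generality_correlation(prof)$r, -1)
  # degenerate variance errors
  prof$sd_ph <- rep(1, 6)
  expect_error(generality_correlation(prof), "zero variance")
})
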