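test_that("fixed-fixed samplers preserve both margins on every draw", {
  set.seed(5)
  b <- random_binary_matrix(8, 6)
  for (alg in c("curveball", "swap")) {
    draws <- sample_fixed_fixed(b, 40, seed = 99, algorithm = alg)
    expect_length(draws, 40)
    for (d in draws) {
      expect_equal(rowSums(d), rowSums(b))
      expect_equal(colSums(d), colSums(b))
      expect_true(all(d %in% c(0, 1)))
    }
    # the chain actually moves
    expect_true(any(vapply(draws, function(d) any(d != b), logical(1))))
  }
})

test_that("degenerate ensembles are detected", {
  ones <- matrix(1, 3, 3)
  expect_warning(draws <- sample_fixed_fixed(ones, 5, seed = 1),
                 "no margin-preserving perturbation")
  expect_true(all(vapply(draws, function(d) all(d == ones), logical(1))))
  expect_error(sample_fixed_fixed(cbind(c(1, 0), c(1, 0)), 2),
               "all-zero")
})

test_that("the sampler visits the whole two-member checkerboard ensemble", {
  m <- rbind(c(1, 0), c(0, 1))
  draws <- sample_fixed_fixed(m, 60, seed = 3, thin = 3)
  ids <- vapply(draws, function(d) d[1, 1], numeric(1))
  expect_setequal(unique(ids), c(0, 1))
})

test_that("quantitative null schemes preserve their stated constraints", {
  set.seed(8)
  cnt <- matrix(rpois(24, 3) + rbinom(24, 1, 0.5), 6, 4)
  cnt[1, ] <- cnt[1, ] + 1  # avoid empty rows
  # margins_fixed: both quantitative margins exact
  draws <- sample_weighted_null(cnt, 30, seed = 4, scheme = "margins_fixed")
  for (d in draws) {
    expect_equal(rowSums(d), rowSums(cnt))
    expect_equal(colSums(d), colSums(cnt))
  }
  # rescaling via an underlying count matrix reproduces the observed scale
  sizes <- c(5, 10, 8, 4)
  rel <- sweep(cnt, 2, sizes, "/") * 100
  draws <- sample_weighted_null(rel, 10, seed = 4, scheme = "margins_fixed",
                                counts = cnt)
  for (d in draws) expect_equal(colSums(d), colSums(rel))
  expect_error(
    sample_weighted_null(rel, 2, scheme = "margins_fixed"),
    "integer count matrix")

  # skeleton_shuffle: value multiset and zero count preserved
  skel_ok <- rbind(c(4, 2, 0), c(1, 0, 3), c(0, 5, 1))
  draws <- sample_weighted_null(skel_ok, 30, seed = 5,
                                scheme = "skeleton_shuffle")
  for (d in draws) {
    expect_equal(sort(d[d > 0]), sort(skel_ok[skel_ok > 0]))
    expect_equal(sum(d == 0), sum(skel_ok == 0))
  }
  # within-row permutation: row multisets preserved
  draws <- sample_weighted_null(skel_ok, 10, seed = 6,
                                scheme = "cell_permute_within_rows")
  for (d in draws) {
    for (i in 1:3) expect_equal(sort(d[i, ]), sort(skel_ok[i, ]))
  }
})

test_that("skeleton-shuffle null mean matches the exhaustive tiny ensemble", {
  m <- rbind(c(3, 1, 0), c(2, 0, 1), c(0, 4, 2))
  skel <- (m > 0) * 1
  vals <- m[m > 0]
  # oracle: every fixed-fixed skeleton x every assignment of the values
  skels <- oracle_fixed_fixed_ensemble(rowSums(skel), colSums(skel))
  wn <- c()
  perms <- oracle_perms(length(vals))
  for (s in skels) {
    pos <- which(s > 0)
    for (p in seq_len(nrow(perms))) {
      x <- s
      x[pos] <- vals[perms[p, ]]
      wn <- c(wn, oracle_wnodf(x, "columns"))
    }
  }
  exact_mean <- mean(wn)
  draws <- sample_weighted_null(m, 600, seed = 11,
                                scheme = "skeleton_shuffle")
  sim <- vapply(draws, function(d) wnodf(d, "columns"), numeric(1))
  se <- sd(sim) / sqrt(length(sim))
  expect_lt(abs(mean(sim) - exact_mean), 3 * se + 1e-9)
})

test_that("nestedness_test recovers both signatures on a study-shaped dataset", {
  # seed-fixed synthetic dataset carrying the nested-incidence /
  # anti-nested-abundance structure at study scale (50 phylotypes, 6 sites)
  cfg <- simulation_config(regime = "nested", dominance_shift = TRUE,
                           seed = 101)
  sim <- suppressMessages(simulate_communities(cfg))
  pooled <- suppressMessages(pool_to_matrix(sim$samples))
  pooled <- sort_rows_by_occurrence(sort_columns_by_gradient(pooled))
  rel <- normalize_relative_abundance(pooled, attr(sim$samples, "groups"))
  pres <- to_presence_absence(rel)

  res <- nestedness_test(pres, "nodf", "columns", n_null = 199, seed = 2)
  expect_s3_class(res, "nestedness_result")
  expect_equal(res$observed, nodf(pres, "columns"))
  expect_equal(res$z, (res$observed - res$null_mean) / res$null_sd)
  expect_gte(res$p_upper, 1 / 200)
  expect_gte(res$p_lower, 1 / 200)
  expect_gt(res$z, 0)
  expect_lte(res$p_upper, 0.05)

  wres <- nestedness_test(rel, "wnodf", "rows", n_null = 199, seed = 2,
                          counts = pooled)
  expect_lt(wres$z, 0)
  expect_lte(wres$p_lower, 0.01)
  expect_equal(wres$observed, wnodf(rel, "rows"))

  # determinism under a fixed seed
  res2 <- nestedness_test(pres, "nodf", "columns", n_null = 199, seed = 2)
  expect_equal(res$null_mean, res2$null_mean)
  expect_equal(res$p_upper, res2$p_upper)
  # kind guards
  expect_error(nestedness_test(pres, "wnodf", "columns"), "quantitative")
  expect_error(nestedness_test(rel, "nodf", "columns"), "presence")
})
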