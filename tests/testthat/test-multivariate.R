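test_that("distance functions evaluate their closed forms", {
  expect_equal(jaccard_distance(c(1, 1, 1), c(1, 1, 0)), 1 / 3)
  expect_equal(jaccard_distance(c(1, 0), c(1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0), c(0, 1)), 1)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "empty union")

  expect_equal(morisita_horn_distance(c(2, 4), c(1, 2)), 0)
  expect_equal(morisita_horn_distance(c(3, 0), c(0, 7)), 1)
  expect_equal(morisita_horn_distance(c(1, 1), c(1, 3)), 1 / 9)
  expect_error(morisita_horn_distance(c(0, 0), c(1, 1)), "zero total")

  expect_equal(ruzicka_distance(c(2, 1), c(2, 1)), 0)
  expect_equal(ruzicka_distance(c(2, 0), c(0, 3)), 1)
  expect_equal(ruzicka_distance(c(3, 1, 0), c(1, 1, 2)), 2 / 3)
})

test_that("distances are symmetric, bounded, and match vegan", {
  set.seed(21)
  for (k in seq_len(50)) {
    x <- rpois(8, 2) + rbinom(8, 1, 0.3)
    y <- rpois(8, 2) + rbinom(8, 1, 0.3)
    if (sum(x) == 0 || sum(y) == 0) next
    for (f in list(jaccard_distance, morisita_horn_distance,
                   ruzicka_distance)) {
      d <- f(x, y)
      expect_gte(d, 0)
      expect_lte(d, 1 + 1e-12)
      expect_equal(d, f(y, x))
      expect_equal(f(x, x), 0, tolerance = 1e-12)
    }
  }
  skip_if_not_installed("vegan")
  set.seed(22)
  m <- matrix(rpois(30, 2) + 1, 5, 6)
  expect_equal(
    as.vector(community_distance(m, "jaccard", along = "rows")),
    as.vector(vegan::vegdist((m > 0) * 1, "jaccard")))
  expect_equal(
    as.vector(community_distance(m, "morisita_horn", along = "rows")),
    as.vector(vegan::vegdist(m, "horn")))
  expect_equal(
    as.vector(community_distance(m, "ruzicka", along = "rows")),
    as.vector(vegan::vegdist(m, "jaccard")))
})

test_that("one-way PERMANOVA p equals exhaustive label enumeration", {
  set.seed(31)
  pts <- matrix(rnorm(12), 6, 2)
  pts[4:6, ] <- pts[4:6, ] + 1.5
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 3)
  res <- permanova_oneway(d, g, exact = TRUE)
  # oracle: every permutation, pseudo-F from the printed formula
  dm <- as.matrix(d)
  perms <- oracle_perms(6)
  f_all <- apply(perms, 1, function(p) oracle_pseudo_f(dm, g[p]))
  f_obs <- oracle_pseudo_f(dm, g)
  expect_equal(res$terms$pseudo_f, f_obs, tolerance = 1e-12)
  expect_equal(res$terms$p, mean(f_all >= f_obs - 1e-12))
  # only choose(6,3) = 20 distinct assignments exist
  expect_equal(length(unique(round(f_all, 10))) <= 20, TRUE)
})

test_that("pseudo-F matches the vegan reference and is label-invariant", {
  skip_if_not_installed("vegan")
  set.seed(32)
  comm <- matrix(rbinom(60, 1, 0.5), 12, 5)
  comm[rowSums(comm) == 0, 1] <- 1
  d <- community_distance(comm, "jaccard", along = "rows")
  g <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova_oneway(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$terms$pseudo_f, ref$F[1], tolerance = 1e-10)
  # invariant to relabeling and reordering of units
  g2 <- c(a = "x", b = "y", c = "z")[g]
  expect_equal(permanova_oneway(d, g2, n_perm = 9, seed = 1)$terms$pseudo_f,
               mine$terms$pseudo_f)
  ord <- sample(12)
  expect_equal(
    permanova_oneway(as.matrix(d)[ord, ord], g[ord], n_perm = 9,
                     seed = 1)$terms$pseudo_f,
    mine$terms$pseudo_f, tolerance = 1e-10)
})

test_that("two-way PERMANOVA partitions a balanced crossed design", {
  set.seed(33)
  a <- rep(c("inocA", "inocB"), each = 15)
  b <- rep(rep(c("pH3", "pH4", "pH5"), each = 5), 2)
  base <- matrix(rnorm(30 * 4), 30, 4)
  base[a == "inocA", ] <- base[a == "inocA", ] + 2  # factor A signal only
  d <- dist(base)
  res <- permanova_twoway(d, a, b, n_perm = 199, seed = 9)
  expect_equal(res$terms$df, c(1, 2, 2, 24))
  expect_lt(res$terms$p[1], 0.05)
  expect_gt(res$terms$p[2], 0.05)
  expect_gt(res$terms$p[3], 0.05)
  # sums of squares add to the total
  dm <- as.matrix(d)
  ss_tot <- sum(dm[upper.tri(dm)]^2) / 30
  expect_equal(sum(res$terms$ss), ss_tot, tolerance = 1e-8)
  expect_error(permanova_twoway(d, a, c(b[-1], "pH9")), "balanced")

  skip_if_not_installed("vegan")
  df <- data.frame(a = a, b = b)
  ref <- vegan::adonis2(d ~ a * b, data = df, permutations = 49,
                        by = "terms")
  expect_equal(res$terms$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(res$terms$ss, ref$SumOfSqs[1:4], tolerance = 1e-8)
})

test_that("Mantel r and exact p equal the enumeration oracle", {
  set.seed(34)
  env <- c(s1 = 3.5, s2 = 4.2, s3 = 5.9, s4 = 7.1)
  comm <- matrix(rpois(20, 3), 4, 5,
                 dimnames = list(names(env), NULL))
  d1 <- community_distance(comm, "morisita_horn", along = "rows")
  d2 <- env_distance(env)
  res <- mantel_test(d1, d2, exact = TRUE)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  lt <- lower.tri(m1)
  r_hand <- cor(m1[lt], m2[lt])
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  perms <- oracle_perms(4)
  r_all <- apply(perms, 1, function(p) cor(m1[lt], m2[p, p][lt]))
  expect_equal(res$p, mean(r_all >= r_hand - 1e-12))
  # identity: r = 1
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$r, 1)
  # label permutation of both matrices leaves r unchanged
  p <- sample(4)
  expect_equal(mantel_test(m1[p, p], m2[p, p], n_perm = 9, seed = 1)$r,
               res$r)
  skip_if_not_installed("vegan")
  expect_equal(vegan::mantel(d1, d2, permutations = 0)$statistic, res$r,
               tolerance = 1e-12)
})
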