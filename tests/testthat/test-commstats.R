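test_that("relative abundance standardises rows to unit total", {
  m <- rbind(s1 = c(10, 30, 60), s2 = c(1, 1, 2))
  ra <- relative_abundance(m)
  expect_equal(unname(ra["s1", ]), c(0.1, 0.3, 0.6))
  expect_equal(unname(rowSums(ra)), c(1, 1))
  expect_error(relative_abundance(rbind(s1 = c(1, 2), bad = c(0, 0))), "bad")
})

test_that("distance constructors return valid symmetric matrices", {
  set.seed(61)
  m <- matrix(runif(20), 5)
  m[, 1] <- 1  # no empty community rows
  for (d in list(euclidean_distance(m), sorensen_distance(m > 0.5))) {
    dm <- as.matrix(d)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 5))
    expect_true(all(dm >= 0))
  }
  expect_equal(as.matrix(euclidean_distance(rbind(c(1, 0), c(0, 1))))[1, 2],
               sqrt(2))
})

test_that("Sorensen dissimilarity follows 1 - 2a/(2a+b+c)", {
  m <- rbind(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0), z = c(1, 1, 0, 0),
             w = c(0, 0, 0, 1))
  d <- as.matrix(sorensen_distance(m))
  expect_equal(d["x", "z"], 0)            # identical sets
  expect_equal(d["x", "w"], 1)            # disjoint non-empty sets
  expect_equal(d["x", "y"], 0.5)          # a = 1, b = 1, c = 1
  expect_warning(sorensen_distance(rbind(c(0, 0), c(0, 0))), "empty")
})

test_that("Sorensen agrees with the vegan oracle on random communities", {
  skip_if_not_installed("vegan")
  set.seed(62)
  m <- matrix(rbinom(60, 1, 0.5), 6)
  m[1, ] <- pmax(m[1, ], 1)  # avoid empty rows
  got <- as.matrix(sorensen_distance(m))
  want <- as.matrix(vegan::vegdist(m, method = "bray", binary = TRUE))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("Mantel r is exact on self-comparison and matches vegan", {
  set.seed(63)
  x <- matrix(rnorm(14), 7)
  d1 <- dist(x)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1.0)
  d2 <- dist(matrix(rnorm(14), 7))
  got <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  skip_if_not_installed("vegan")
  want <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(got$r, unname(want$statistic), tolerance = 1e-12)
})

test_that("Mantel p on 4-sample toys equals exhaustive enumeration", {
  set.seed(64)
  for (trial in 1:5) {
    m1 <- as.matrix(dist(matrix(rnorm(8), 4)))
    m2 <- as.matrix(dist(matrix(rnorm(8), 4)))
    got <- mantel_test(m1, m2, exact = TRUE)
    # independent oracle: enumerate all 4! = 24 joint label permutations
    perms <- ednabar:::.permutations(4)
    ut <- upper.tri(m1)
    r_obs <- cor(m1[ut], m2[ut])
    rs <- apply(perms, 1, function(p) cor(m1[ut], m2[p, p][ut]))
    expect_equal(got$p, mean(abs(rs) >= abs(r_obs) - 1e-12))
    expect_equal(got$r, r_obs)
  }
})

test_that("Mantel is deterministic per seed and flags constant input", {
  set.seed(65)
  d1 <- dist(matrix(rnorm(12), 6)); d2 <- dist(matrix(rnorm(12), 6))
  a <- mantel_test(d1, d2, n_perm = 199, seed = 9)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 9)
  expect_identical(a, b)
  expect_warning(m <- mantel_test(matrix(0, 4, 4), d2 = as.matrix(d2)[1:4, 1:4]),
                 "constant")
  expect_true(is.na(m$r))
})

test_that("PERMANOVA pseudo-F equals hand arithmetic on a 4-sample toy", {
  # groups {1,2} and {3,4}; hand-built distances
  dm <- matrix(0, 4, 4)
  dm[1, 2] <- dm[2, 1] <- 1
  dm[3, 4] <- dm[4, 3] <- 2
  dm[1, 3] <- dm[3, 1] <- 5
  dm[1, 4] <- dm[4, 1] <- 5
  dm[2, 3] <- dm[3, 2] <- 5
  dm[2, 4] <- dm[4, 2] <- 5
  # SS_total = (1 + 4 + 4*25)/4 = 26.25; SS_within = 1/2 + 4/2 = 2.5
  # F = (26.25 - 2.5)/1 / (2.5/2) = 23.75/1.25 = 19
  res <- permanova(dm, c("a", "a", "b", "b"), n_perm = 99, seed = 1,
                   pairwise = FALSE)
  expect_equal(res$pseudo_F, 19)
})

test_that("PERMANOVA agrees with the vegan oracle and separates far groups", {
  skip_if_not_installed("vegan")
  set.seed(66)
  x <- matrix(rnorm(24), 12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dist(x)
  got <- permanova(d, g, n_perm = 199, seed = 2, pairwise = FALSE)
  df <- data.frame(g = g)
  want <- vegan::adonis2(d ~ g, data = df, permutations = 199)
  expect_equal(got$pseudo_F, want$F[1], tolerance = 1e-10)

  # identical point clouds shifted far apart: minimum achievable p
  y <- rbind(x[1:6, ], x[1:6, ] + 100)
  res <- permanova(dist(y), rep(c("a", "b"), each = 6), n_perm = 199,
                   seed = 3, pairwise = FALSE)
  expect_equal(res$p, 1 / 200)
  expect_error(permanova(d, c(rep("a", 11), "b")), "single sample")
})

test_that("pairwise PERMANOVA tests each group pair", {
  set.seed(67)
  x <- rbind(matrix(rnorm(10), 5), matrix(rnorm(10), 5) + 10,
             matrix(rnorm(10), 5) + 20)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- permanova(dist(x), g, n_perm = 99, seed = 4)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p <= 0.05))
})

test_that("PERMDISP distances to centroid match the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(68)
  x <- matrix(rnorm(30), 10)
  g <- rep(c("a", "b"), each = 5)
  d <- dist(x)
  got <- permdisp(d, g, n_perm = 99, seed = 5)
  want <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(got$distances), unname(want$distances),
               tolerance = 1e-8)
  # a duplicated point cloud has zero dispersion -> small p vs dispersed group
  y <- rbind(matrix(rnorm(10), 5) * 3, matrix(rep(c(1, 2), each = 5), 5))
  res <- permdisp(dist(y), g, n_perm = 199, seed = 6)
  expect_lt(res$p, 0.05)
  expect_equal(unname(res$group_means["b"]), 0)
})

test_that("nMDS recovers planar configurations with near-zero stress", {
  set.seed(69)
  pts <- matrix(rnorm(16), 8)
  d <- dist(pts)
  fit <- nmds(d, k = 2, n_starts = 4, seed = 7)
  expect_lt(fit$stress, 0.02)
  # recovered distances correlate with the originals in rank
  expect_gt(cor(dist(fit$points), d, method = "spearman"), 0.95)
  # stress trace is non-increasing
  expect_true(all(diff(fit$stress_trace) <= 1e-8))
})

test_that("nMDS handles the equilateral and degenerate cases", {
  tri <- matrix(1, 3, 3) - diag(3)
  fit <- suppressWarnings(nmds(tri, k = 2, n_starts = 2, seed = 8))
  expect_lt(fit$stress, 1e-3)
  expect_error(nmds(tri, k = 3), "at least")
  expect_warning(nmds(matrix(1, 5, 5) - diag(5), k = 2, seed = 9),
                 "degenerate")
})

test_that("rarefaction expectation is exact at the endpoints and monotone", {
  counts <- c(50, 30, 15, 4, 1)
  N <- sum(counts)
  curve <- rarefaction_curve(counts, c(1, 10, 50, N))
  expect_equal(curve$expected_richness[1], 1)  # one read, one taxon
  expect_equal(curve$expected_richness[length(curve$depth)], 5)
  expect_true(all(diff(curve$expected_richness) >= 0))
  expect_equal(rarefaction_curve(c(40), c(1, 10, 40))$expected_richness,
               c(1, 1, 1))
  expect_error(rarefaction_curve(counts, N + 1), "exceeds")
})

test_that("rarefaction matches vegan and Monte-Carlo subsampling", {
  skip_if_not_installed("vegan")
  counts <- c(120, 60, 30, 10, 5, 2, 1)
  depths <- c(5, 20, 80)
  got <- rarefaction_curve(counts, depths)$expected_richness
  want <- as.numeric(vegan::rarefy(counts, depths))
  expect_equal(got, want, tolerance = 1e-10)

  set.seed(70)
  pool <- rep(seq_along(counts), counts)
  B <- 400
  for (k in seq_along(depths)) {
    sims <- replicate(B, length(unique(sample(pool, depths[k]))))
    se <- sd(sims) / sqrt(B)
    expect_lt(abs(got[k] - mean(sims)), 3 * se + 1e-9)
  }
})

test_that("permutation p-values stay within (0, 1]", {
  set.seed(71)
  d1 <- dist(matrix(rnorm(12), 6)); d2 <- dist(matrix(rnorm(12), 6))
  p1 <- mantel_test(d1, d2, n_perm = 49, seed = 1)$p
  p2 <- permanova(d1, rep(c("a", "b"), 3), n_perm = 49, seed = 1,
                  pairwise = FALSE)$p
  p3 <- permdisp(d1, rep(c("a", "b"), 3), n_perm = 49, seed = 1)$p
  for (p in c(p1, p2, p3)) {
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})
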