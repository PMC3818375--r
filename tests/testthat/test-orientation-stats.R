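# Spherical representation, stereoplot, permutation machinery.

test_that("canonicalization is idempotent and antipodally consistent", {
  set.seed(1)
  a <- matrix(stats::rnorm(300), ncol = 3)
  c1 <- canonicalize_axes(a)
  expect_equal(canonicalize_axes(c1), c1)
  expect_equal(canonicalize_axes(-a), c1)
  expect_equal(rowSums(c1^2), rep(1, 100))
  expect_true(all(c1[, 3] >= -1e-9))
  expect_error(canonicalize_axes(c(0, 0, 0)), "zero axis")
})

test_that("stereoplot: pole, equator, round trip", {
  expect_equal(stereo_project(data.frame(longitude = 0, latitude = 90)),
               data.frame(x = 0, y = 0))
  eq <- stereo_project(data.frame(longitude = 0, latitude = 0))
  expect_equal(sqrt(eq$x^2 + eq$y^2), 1) # tan(45 deg)
  set.seed(2)
  ll <- to_lonlat(matrix(stats::rnorm(300), ncol = 3))
  back <- stereo_unproject(stereo_project(ll))
  expect_equal(back$latitude, ll$latitude, tolerance = 1e-9)
  expect_equal(back$longitude, ll$longitude, tolerance = 1e-9)
})

test_that("haversine: quarter circle, identity, axial identification, acos-dot", {
  expect_equal(haversine_deg(data.frame(longitude = 0, latitude = 0),
                             data.frame(longitude = 90, latitude = 0)), 90)
  expect_equal(haversine_deg(data.frame(longitude = 33, latitude = 21),
                             data.frame(longitude = 33, latitude = 21)), 0)
  # antipodal pair with axial identification
  a <- data.frame(longitude = 10, latitude = 0)
  b <- data.frame(longitude = 190, latitude = 0)
  expect_equal(haversine_deg(a, b, axial = TRUE), 0)
  # equals acos of the dot product (non-axial) on random upper-hemisphere pairs
  set.seed(3)
  u <- canonicalize_axes(matrix(stats::rnorm(60), ncol = 3))
  v <- canonicalize_axes(matrix(stats::rnorm(60), ncol = 3))
  hd <- haversine_deg(u, v)
  ad <- acos(pmin(1, pmax(-1, rowSums(u * v)))) * 180 / pi
  expect_equal(hd, ad, tolerance = 1e-9)
})

test_that("spherical centroid: identity, symmetry, degenerate", {
  a <- canonicalize_axes(c(0.3, -0.2, 0.9))[1, ]
  expect_equal(spherical_centroid(matrix(a, 1)), a)
  two <- rbind(c(sin(10 * pi / 180), 0, cos(10 * pi / 180)),
               c(-sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  expect_equal(spherical_centroid(two), c(0, 0, 1), tolerance = 1e-6)
  # two canonical axes cancelling on the equator: no meaningful centroid
  expect_error(spherical_centroid(rbind(c(-1, 0, 0), c(1, 0, 1e-7))),
               "dispersed")
})

test_that("median permutation test matches the brute-force enumerator", {
  # frozen oracle value for the two-cluster case (enumerated independently)
  r <- permutation_test_median(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.2)
  expect_equal(r$n_allocations, 20)
  expect_equal(r$mode, "exhaustive")
  # all-tied groups
  expect_equal(permutation_test_median(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # random instances across sizes, exhaustive vs independent oracle
  set.seed(4)
  for (sz in list(c(3, 3), c(4, 2), c(5, 4), c(5, 5))) {
    a <- stats::rnorm(sz[1]); b <- stats::rnorm(sz[2], 1)
    expect_equal(permutation_test_median(a, b)$p_value,
                 oracle_perm_median(a, b))
    # label symmetry
    expect_equal(permutation_test_median(b, a)$p_value,
                 permutation_test_median(a, b)$p_value)
  }
  expect_error(permutation_test_median(numeric(0), 1), "empty")
})

test_that("spherical permutation test matches the brute-force enumerator", {
  set.seed(5)
  # two tight clusters 40 degrees apart, n = 3 + 3 -> p = 2/20
  A <- sample_axes(c(0, 0, 1), 500, 3, seed = 1)
  B <- sample_axes(sagittal_axis(40), 500, 3, seed = 2)
  r <- permutation_test_sphere(A, B)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, oracle_perm_sphere(A, B))
  for (sz in list(c(3, 4), c(5, 5), c(4, 2))) {
    A <- sample_axes(c(0.2, 0.1, 1), 8, sz[1], seed = sz[1])
    B <- sample_axes(c(0, 0.3, 1), 8, sz[2], seed = 10 + sz[2])
    expect_equal(permutation_test_sphere(A, B)$p_value, oracle_perm_sphere(A, B))
    expect_equal(permutation_test_sphere(B, A)$p_value,
                 permutation_test_sphere(A, B)$p_value)
  }
  # outlier-exclusion option drops the named row
  A2 <- sample_axes(c(0, 0, 1), 30, 5, seed = 3)
  B2 <- sample_axes(sagittal_axis(25), 30, 5, seed = 4)
  r_full <- permutation_test_sphere(A2, B2)
  r_excl <- permutation_test_sphere(A2, B2, exclude = list(a = 5))
  expect_equal(r_excl$n_allocations, choose(9, 4))
  expect_false(isTRUE(all.equal(r_full$statistic, r_excl$statistic)))
})

test_that("Monte-Carlo p falls in the exact p's 99% binomial interval", {
  set.seed(6)
  a <- stats::rnorm(8); b <- stats::rnorm(8, 0.8)
  exact <- permutation_test_median(a, b)$p_value
  mc <- permutation_test_median(a, b, max_exhaustive = 10, n_draws = 1e4,
                                seed = 1)
  expect_equal(mc$mode, "monte_carlo")
  # recover the raw hit count from the (k+1)/(n+1) estimator and compare the
  # unbiased proportion against the exact p's 99% binomial interval
  k <- mc$p_value * (1e4 + 1) - 1
  half <- stats::qnorm(0.995) * sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(k / 1e4 - exact), half)
  expect_gte(mc$p_value, 1 / (1e4 + 1))
})

test_that("exact rank-sum: closed cases, oracle, normal approximation", {
  expect_equal(exact_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(exact_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(7)
  for (sz in list(c(4, 4), c(5, 3), c(5, 5))) {
    a <- stats::rnorm(sz[1]); b <- stats::rnorm(sz[2], 0.5)
    expect_equal(exact_rank_sum(a, b), oracle_rank_sum(a, b))
  }
  # ties handled via midranks, against the oracle that uses the same ranks
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(exact_rank_sum(a, b), oracle_rank_sum(a, b))
  # large-sample agreement with the normal approximation at n = 15 + 15
  set.seed(8)
  a <- stats::rnorm(15); b <- stats::rnorm(15, 0.6)
  p_exact <- exact_rank_sum(a, b)
  p_norm <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.02)
})
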