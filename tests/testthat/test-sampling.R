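test_that("method-of-moments beta recovers the uniform and stays mean-exact", {
  # uniform has sd sqrt(1/12)
  expect_equal(unname(beta_shapes_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-10)
  # plug-in case: mean 0.842, effective sd 0.0364 -> nu ~ 99.41
  sh <- beta_shapes_from_moments(0.842, 0.0364)
  expect_equal(unname(sh), c(83.70117, 15.70639), tolerance = 1e-4)
  # quadrature check that the fitted density has the requested mean
  q <- integrate(function(x) x * dbeta(x, sh[1], sh[2]), 0, 1)$value
  expect_equal(q, 0.842, tolerance = 1e-8)
  # vanishing variance collapses to an atom at the mean
  expect_null(beta_shapes_from_moments(0.5, 0))
  expect_equal(beta_spec(0.5, 0)$family, "degenerate")
  # infeasible spread points at the n_eff override
  expect_error(beta_shapes_from_moments(0.5, 0.6), "beta_n_eff")
})

test_that("triangular specs have the closed-form mean and honour their support", {
  spec <- triangular_spec(0.3, 0.675, 0.85) # a registry utility row
  expect_equal(spec_mean(spec), (0.3 + 0.675 + 0.85) / 3)
  expect_equal(spec_mean(spec), 0.6083333, tolerance = 1e-6)
  x <- sample_dist(triangular_spec(0, 0.5, 1), 5000, seed = 42)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(triangular_spec(0.5, 0.5, 0.5)$family, "degenerate")
  expect_error(triangular_spec(0.9, 0.5, 1), "ordering")
})

test_that("lognormal specs preserve the median and match the bound-derived scale", {
  spec <- lognormal_spec_from_bounds(0.66, 0.65, 0.72)
  expect_equal(unname(spec$params["sdlog"]), 0.0260920, tolerance = 1e-6)
  expect_equal(exp(spec$params[["meanlog"]]), 0.66)
  x <- sample_dist(lognormal_spec_from_bounds(2, 1, 4), 2e5, seed = 7)
  expect_equal(median(x), 2, tolerance = 0.01)
  expect_equal(lognormal_spec_from_bounds(1, 1, 1)$family, "degenerate")
  expect_error(lognormal_spec_from_bounds(1, -0.1, 2), "positive")
})

test_that("empirical means match analytic means within 3 standard errors", {
  specs <- list(
    beta = beta_spec(0.842, 0.364005, n_eff = 100),
    triangular = triangular_spec(0.3, 0.675, 0.85),
    normal = normal_spec(68, 51.9, 81.3, support = c(0, 100)),
    lognormal = lognormal_spec_from_bounds(0.66, 0.65, 0.72))
  n <- 1e5
  for (nm in names(specs)) {
    x <- sample_dist(specs[[nm]], n, seed = substream_seed(1, nm))
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - spec_mean(specs[[nm]])), 3 * se, label = nm)
  }
})

test_that("truncation keeps probabilities, utilities, ages and HRs in range", {
  x <- sample_dist(normal_spec(2, -50, 54, support = c(0, 100)), 2e4, seed = 3)
  expect_true(all(x >= 0 & x <= 100))
  x <- sample_dist(beta_spec(0.92, 0.305173, n_eff = 4), 2e4, seed = 3)
  expect_true(all(x >= 0 & x <= 1))
  x <- sample_dist(lognormal_spec_from_bounds(0.66, 0.3, 1.4), 2e4, seed = 3)
  expect_true(all(x > 0))
})

test_that("degenerate specs yield constant sequences regardless of seed", {
  expect_equal(sample_dist(degenerate_spec(0.5), 10, seed = 1), rep(0.5, 10))
  expect_equal(sample_dist(degenerate_spec(0.5), 10, seed = 99), rep(0.5, 10))
})

test_that("seeded draws are reproducible and substreams are independent", {
  spec <- beta_spec(0.842, 0.364005)
  s1 <- substream_seed(11, "disease A", "surv_altern")
  expect_identical(sample_dist(spec, 100, seed = s1),
                   sample_dist(spec, 100, seed = s1))
  # a different master seed changes the draws
  s2 <- substream_seed(12, "disease A", "surv_altern")
  expect_false(identical(sample_dist(spec, 100, seed = s1),
                         sample_dist(spec, 100, seed = s2)))
  # an unrelated parameter's substream does not collide
  s3 <- substream_seed(11, "disease A", "qol_altern")
  expect_false(s1 == s3)
  expect_false(identical(sample_dist(spec, 100, seed = s1),
                         sample_dist(spec, 100, seed = s3)))
  # sampling leaves the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(sample_dist(spec, 10, seed = s1))
  expect_identical(.Random.seed, before)
})
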