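test_that("delay grid is arithmetic, inclusive, with optional permanent scenario", {
  expect_equal(build_delay_grid(2, 10, 52), c(2, 12, 22, 32, 42, 52))
  expect_equal(build_delay_grid(2, 25, 52), c(2, 27, 52))
  expect_equal(build_delay_grid(2, 10, 52, include_permanent = TRUE),
               c(2, 12, 22, 32, 42, 52, Inf))
})

test_that("occupancies are conserved, deceased is monotone, bounds hold", {
  cfgs <- list(model_config(), reference_config())
  params <- list(u_alt = 0.675, u_surg = 0.9, lambda_alt = 0.24, lambda_surg = 0.054,
                 age = 68)
  for (cfg in cfgs) {
    for (d in c(2, 52, Inf)) {
      tr <- run_cohort(params, d, cfg)
      occ <- tr$alternative + tr$surgery + tr$deceased
      expect_true(all(abs(occ - 1) < 1e-10))
      expect_true(all(diff(tr$deceased) >= -1e-12))
      expect_true(all(tr$alternative >= 0 & tr$alternative <= 1))
      expect_true(all(tr$surgery >= 0 & tr$surgery <= 1))
    }
  }
})

test_that("immortal full-health cohort accrues exactly its simulated horizon", {
  cfg <- model_config(discount_rate = 0)
  params <- list(u_alt = 1, u_surg = 1, lambda_alt = 0, lambda_surg = 0, age = 68)
  tr <- run_cohort(params, 12, cfg)
  n_cycles <- nrow(tr) - 1
  expect_equal(discounted_qalys(tr), n_cycles * 7 / 365.25, tolerance = 1e-12)
  # trace ends at max_age (to within half a cycle of rounding)
  expect_equal(68 + tr$time[nrow(tr)], 100, tolerance = 0.01)
  expect_true(all(tr$alternative + tr$surgery == 1))
  # zero utilities accrue nothing
  tr0 <- run_cohort(list(u_alt = 0, u_surg = 0, lambda_alt = 0.1, lambda_surg = 0.1,
                         age = 68), 12, cfg)
  expect_equal(discounted_qalys(tr0), 0)
})

test_that("a lethal alternative arm never populates the surgery state appreciably", {
  tr <- run_cohort(list(u_alt = 0.7, u_surg = 0.9, lambda_alt = 200, lambda_surg = 0.05,
                        age = 68), 52, model_config())
  expect_lt(max(tr$surgery), 1e-10)
  expect_gt(tr$deceased[nrow(tr)], 1 - 1e-10)
})

test_that("closed form matches independent numerical integration to 1e-8", {
  u_a <- 0.675; u_s <- 0.9
  la <- -log(0.488) / 3; ls <- -log(0.874) / 2.5; r <- 0.015
  D <- 50 / (365.25 / 7); Tt <- 32
  f <- function(t) ifelse(t < D, u_a * exp(-(la + r) * t),
                          u_s * exp(-(la + r) * D - (ls + r) * (t - D)))
  quad <- integrate(f, 0, D, rel.tol = 1e-12)$value +
    integrate(f, D, Tt, rel.tol = 1e-12)$value
  expect_equal(closed_form_qaly(u_a, u_s, la, ls, r, D, Tt), quad, tolerance = 1e-8)
  # boundary: zero delay is the pure surgery annuity
  expect_equal(closed_form_qaly(0.7, 0.9, 0.1, 0.05, 0.015, 0, 30),
               0.9 * (1 - exp(-0.065 * 30)) / 0.065, tolerance = 1e-12)
  # undiscounted immortal limit
  expect_equal(closed_form_qaly(0.7, 0.9, 0, 0, 0, 1, 30), 0.7 * 1 + 0.9 * 29,
               tolerance = 1e-10)
})

test_that("weekly-cycle cohort agrees with the closed form within 0.5% over 100 random sets", {
  set.seed(20260101)
  worst <- 0
  for (i in 1:100) {
    u_a <- runif(1, 0.3, 1); u_s <- runif(1, 0.3, 1)
    la <- runif(1, 0, 0.4); ls <- runif(1, 0, 0.2)
    age <- runif(1, 30, 90)
    d_weeks <- sample(c(2, 12, 32, 52), 1)
    cfg <- model_config()
    tr <- run_cohort(list(u_alt = u_a, u_surg = u_s, lambda_alt = la,
                          lambda_surg = ls, age = age), d_weeks, cfg)
    horizon <- (nrow(tr) - 1) * 7 / 365.25
    cf <- closed_form_qaly(u_a, u_s, la, ls, cfg$discount_rate,
                           d_weeks * 7 / 365.25, horizon)
    rel <- abs(discounted_qalys(tr) - cf) / cf
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("identical arms give exactly zero DALYs for every scenario", {
  rec <- make_null_record(68, 0.9, 0.05)
  for (d in c(12, 52, Inf)) {
    out <- dalys_per_month(rec, model_config(), reference_weeks = 2, delay_weeks = d)
    expect_identical(out$dalys_per_month, 0)
  }
})

test_that("worse alternative arm makes QALYs strictly decrease with delay", {
  cfg <- model_config()
  vals <- list(u_alt = 0.6, u_surg = 0.9, lambda_alt = 0.2, lambda_surg = 0.05,
               age = 65)
  q <- vapply(build_delay_grid(), function(d)
    discounted_qalys(run_cohort(vals, d, cfg)), numeric(1))
  expect_true(all(diff(q) < 0))
  expect_gt(dalys_per_month(vals, cfg)$dalys_per_month, 0)
})

test_that("equal survivals with better alternative utility give a health gain", {
  vals <- list(u_alt = 0.9, u_surg = 0.85, lambda_alt = 0, lambda_surg = 0, age = 71)
  expect_lt(dalys_per_month(vals, model_config())$dalys_per_month, 0)
})

test_that("removing discounting never decreases discounted QALYs", {
  vals <- list(u_alt = 0.675, u_surg = 0.9, lambda_alt = 0.24, lambda_surg = 0.054,
               age = 68)
  for (d in c(2, 52, Inf)) {
    q0 <- discounted_qalys(run_cohort(vals, d, model_config(discount_rate = 0)))
    q15 <- discounted_qalys(run_cohort(vals, d, model_config(discount_rate = 0.015)))
    expect_gte(q0, q15)
  }
})

test_that("bradycardia point estimate falls within the published interval", {
  out <- dalys_per_month(bradycardia_record(), reference_config())
  expect_gt(out$dalys_per_month, 0.08)
  expect_lt(out$dalys_per_month, 0.19)
})

test_that("life-table mode adds background mortality and shortens survival", {
  vals <- list(u_alt = 0.8, u_surg = 0.8, lambda_alt = 0.02, lambda_surg = 0.02,
               age = 65)
  q_cap <- discounted_qalys(run_cohort(vals, 2, model_config()))
  q_lt <- discounted_qalys(run_cohort(vals, 2, reference_config()))
  expect_lt(q_lt, q_cap)
  lt <- synthetic_life_table()
  expect_true(all(diff(lt$annual_mortality_rate) > 0))
  expect_error(model_config(horizon_mode = "life_table"), "life_table")
})
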