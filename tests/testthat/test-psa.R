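test_that("an all-degenerate record gives the deterministic value with a zero-width interval", {
  rec <- degenerate_effect_record()
  out <- run_psa(rec, model_config(), n_iterations = 50, seed = 1)
  det <- dalys_per_month(rec, model_config())$dalys_per_month
  expect_equal(out$mean_daly_per_month, det, tolerance = 1e-12)
  expect_equal(out$ci_low, out$ci_high)
  expect_equal(out$ci_low, det, tolerance = 1e-12)
})

test_that("the PSA is reproducible from its seed and stable across seeds", {
  rec <- bradycardia_record()
  cfg <- reference_config()
  a <- run_psa(rec, cfg, n_iterations = 200, seed = 7)
  b <- run_psa(rec, cfg, n_iterations = 200, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$mean_daly_per_month, b$mean_daly_per_month)
  c <- run_psa(rec, cfg, n_iterations = 200, seed = 8)
  expect_false(identical(a$draws, c$draws))
  se <- sqrt(sd(a$draws)^2 / 200 + sd(c$draws)^2 / 200)
  expect_lt(abs(a$mean_daly_per_month - c$mean_daly_per_month), 3 * se)
})

test_that("percentile interval brackets the deterministic value as spreads shrink", {
  base <- synthetic_scenario(utility_gap = 0.15, hazard_gap = 0.03, age = 65)
  det <- make_effect_record(synthetic_scenario(utility_gap = 0.15, hazard_gap = 0.03,
                                               age = 65, spread_scale = 0))
  det_val <- run_psa(det$record, model_config(), 20, seed = 1)$mean_daly_per_month
  for (sp in c(0.5, 0.1)) {
    sc <- base; sc$spread_scale <- sp
    rec <- make_effect_record(sc)$record
    out <- run_psa(rec, model_config(), 400, seed = 5)
    expect_lte(out$ci_low, det_val)
    expect_gte(out$ci_high, det_val)
  }
})

test_that("summarize_all covers the registry and collects per-record failures", {
  reg <- surgdelay_registry()[1:3]
  class(reg) <- "comparison_registry"
  res <- summarize_all(reg, model_config(), n_iterations = 50, seed = 2)
  expect_equal(nrow(res$summaries), 3)
  expect_equal(res$grand_mean, mean(res$summaries$mean_daly_per_month))
  # an unresolvable record is reported, not fatal
  broken <- reg
  broken[[2]]$surv_altern <- NULL
  res2 <- summarize_all(broken, model_config(), n_iterations = 50, seed = 2)
  expect_equal(nrow(res2$summaries), 2)
  expect_length(res2$failures, 1)
  expect_warning(summarize_all(structure(list(), class = "comparison_registry")),
                 "empty")
})

test_that("best-alternative selection is the argmin with a lexicographic tie-break", {
  s <- data.frame(disease = "d", surgery = "s", alternative = c("b", "a"),
                  mean_daly_per_month = c(0.05, 0.02))
  expect_equal(select_best_alternative(s)$alternative, "a")
  tie <- data.frame(disease = "d", surgery = "s", alternative = c("zeta", "alpha"),
                    mean_daly_per_month = c(0.02, 0.02))
  expect_equal(select_best_alternative(tie)$alternative, "alpha")
  single <- s[1, ]
  expect_equal(select_best_alternative(single)$alternative, "b")
  expect_error(select_best_alternative(s[0, ]), "no summaries")
})

test_that("ranking sorts descending and is a permutation of the best summaries", {
  toy <- data.frame(disease = c("x", "y", "z"), surgery = "s",
                    alternative = "a", mean_daly_per_month = c(0.3, 0.1, 0.2),
                    ci_low = NA, ci_high = NA)
  rk <- rank_alternatives(toy)
  expect_equal(rk$mean_daly_per_month, c(0.3, 0.2, 0.1))
  expect_equal(rk$rank, 1:3)
  expect_setequal(rk$disease, toy$disease)
  expect_error(rank_alternatives(rbind(toy, toy[1, ])), "duplicate")
})

test_that("for multivessel disease the fixture prefers PCI over medical therapy", {
  reg <- surgdelay_registry()
  mv <- reg[vapply(reg, `[[`, "", "disease") == "Multivessel disease"]
  class(mv) <- "comparison_registry"
  res <- summarize_all(mv, reference_config(), n_iterations = 300, seed = 1)
  expect_equal(select_best_alternative(res$summaries)$alternative, "PCI")
})

test_that("hazard-ratio route and failure guard work end to end", {
  # record resolvable only through the treatment effect
  rec <- bradycardia_record()
  rec$surv_altern <- NULL
  rec$tx_eff <- treatment_effect(2, 1.8, 2.2) # alternative doubles the hazard
  expect_error(run_psa(rec, model_config(), 20, seed = 1), "direction")
  cfg <- model_config(hr_direction = "alternative_vs_surgery")
  out <- run_psa(rec, cfg, 100, seed = 1)
  expect_gt(out$mean_daly_per_month, 0)
  expect_equal(out$n_failed, 0)
})
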