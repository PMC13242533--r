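#' @title Synthetic comparison records with known ground truth
#' @description
#' Generators that emulate the statistical structure of the registry --
#' beta/triangular survival uncertainty, triangular utilities, normal age,
#' lognormal treatment effects -- with controllable effect sizes, so every
#' stage of the pipeline can be tested against closed-form expectations.
#' Synthetic utilities use symmetric triangular spreads, making the sampled
#' mean equal the mode and decoupling engine tests from the mean-versus-mode
#' reading of printed utility ranges.
#' @name synthetic
NULL

#' Null comparison record: identical arms, zero spread
#'
#' Both arms share the same utility and hazard and all spreads are zero, so
#' the DALYs per month are exactly zero and a PSA interval has zero width.
#'
#' @param age Cohort age in years.
#' @param utility Shared utility in \[0, 1\].
#' @param hazard Shared annual hazard (>= 0); expressed as a 5-year survival.
#' @return A [comparison_record()].
#' @export
make_null_record <- function(age, utility, hazard) {
  stopifnot(age >= 0, age < 100, utility >= 0, utility <= 1, hazard >= 0)
  s <- survival_at(hazard, 5)
  surv <- survival_estimate(s, 5, family = "degenerate")
  qol <- utility_estimate(utility, utility, utility)
  comparison_record(disease = "synthetic null", surgery = "surgery",
                    alternative = "alternative",
                    surv_altern = surv, surv_surg = surv,
                    qol_altern = qol, qol_surg = qol,
                    age = age_estimate(age, age, age), sources = "synthetic")
}

#' Synthetic scenario specification
#'
#' @param utility_gap Surgery-arm utility minus alternative-arm utility.
#' @param hazard_gap Alternative-arm hazard minus surgery-arm hazard, per
#'   year.
#' @param age Cohort age, years.
#' @param base_utility,base_hazard Surgery-arm utility and hazard.
#' @param spread_scale Multiplier on all uncertainty spreads (0 = degenerate
#'   record).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(utility_gap = 0.1, hazard_gap = 0.05, age = 65,
                               base_utility = 0.85, base_hazard = 0.03,
                               spread_scale = 1) {
  structure(list(utility_gap = utility_gap, hazard_gap = hazard_gap, age = age,
                 base_utility = base_utility, base_hazard = base_hazard,
                 spread_scale = spread_scale),
            class = "synthetic_scenario")
}

#' Effect record from a synthetic scenario, with its closed-form expectation
#'
#' Builds a record whose alternative arm is worse than its surgery arm by the
#' scenario's utility and hazard gaps, and returns alongside it the expected
#' DALYs per month at point estimates computed from [closed_form_qaly()]
#' (valid for the default `max_age_cap` horizon mode).
#'
#' @param scenario A [synthetic_scenario()].
#' @param config A [model_config()] (used for the discount rate, month length
#'   and horizon of the closed-form expectation).
#' @return List with `record` (a [comparison_record()]) and `expected_daly`
#'   (closed-form DALYs/month at point estimates).
#' @export
make_effect_record <- function(scenario, config = model_config()) {
  u_surg <- scenario$base_utility
  u_alt <- u_surg - scenario$utility_gap
  lambda_surg <- scenario$base_hazard
  lambda_alt <- lambda_surg + scenario$hazard_gap
  if (u_alt < 0 || u_alt > 1 || u_surg > 1 || lambda_alt < 0)
    stop("infeasible scenario: gaps leave the valid parameter range", call. = FALSE)
  sp <- scenario$spread_scale
  tri_u <- function(u) {
    half <- sp * min(0.05, u, 1 - u) # symmetric: sampled mean equals the mode
    utility_estimate(u, u - half, u + half)
  }
  surv <- function(lambda) {
    p <- survival_at(lambda, 5)
    if (sp == 0 || p >= 1)
      survival_estimate(p, 5, family = "degenerate")
    else {
      half <- sp * min(0.02, p / 2, (1 - p) / 2)
      survival_estimate(p, 5, low = p - half, high = p + half, family = "triangular")
    }
  }
  age_half <- sp * 2
  record <- comparison_record(
    disease = "synthetic effect", surgery = "surgery", alternative = "alternative",
    surv_altern = surv(lambda_alt), surv_surg = surv(lambda_surg),
    qol_altern = tri_u(u_alt), qol_surg = tri_u(u_surg),
    age = age_estimate(scenario$age, scenario$age - age_half, scenario$age + age_half),
    sources = "synthetic")
  viol <- validate_record(record)
  if (nrow(viol)) stop("synthetic record invalid: ", paste(viol$rule, collapse = "; "),
                       call. = FALSE)
  dt <- config$cycle_length_weeks / WEEKS_PER_YEAR
  horizon <- round((config$max_age - scenario$age) / dt) * dt
  q <- vapply(c(2, 52) / WEEKS_PER_YEAR, function(d) {
    closed_form_qaly(u_alt, u_surg, lambda_alt, lambda_surg, config$discount_rate,
                     d, horizon)
  }, numeric(1))
  months <- 50 * 7 / config$month_length_days
  list(record = record, expected_daly = (q[1] - q[2]) / months)
}

#' Write a synthetic registry in the standard CSV schema
#'
#' @param n Number of effect records.
#' @param path Output CSV path.
#' @param seed Seed controlling the scenario draws.
#' @return The registry written, invisibly.
#' @export
write_synthetic_registry <- function(n, path, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  records <- lapply(seq_len(n), function(i) {
    sc <- synthetic_scenario(utility_gap = stats::runif(1, -0.1, 0.2),
                             hazard_gap = stats::runif(1, 0, 0.1),
                             age = stats::runif(1, 40, 80))
    rec <- make_effect_record(sc)$record
    rec$disease <- sprintf("synthetic disease %02d", i)
    rec
  })
  reg <- structure(records, class = "comparison_registry")
  write_registry(reg, path)
  invisible(reg)
}
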