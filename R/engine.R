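#' Model configuration
#'
#' Bundles the structural settings of the cohort model.
#'
#' @param discount_rate Annual discount rate on health effects (default 0.015,
#'   the Dutch guideline rate for effects). Discounting is continuous:
#'   `exp(-rate * t)`.
#' @param cycle_length_weeks Cycle length in weeks (default 1, so the delay
#'   grid's week boundaries land exactly on cycles).
#' @param max_age Maximum attainable age in years (default and ceiling 100).
#' @param month_length_days Days per month used to express DALYs per month
#'   (default 30.44 = 365.25/12, so a 50-week delay spans 11.50 months).
#' @param horizon_mode `"max_age_cap"` (individuals face only the disease
#'   hazards and live to at most `max_age`) or `"life_table"` (age-specific
#'   background mortality from `life_table` is added to both arms).
#' @param life_table Data frame with columns `age_years` and
#'   `annual_mortality_rate` (linearly interpolated), required when
#'   `horizon_mode = "life_table"`.
#' @param half_cycle Apply the half-cycle correction (trapezoidal occupancy,
#'   discounting at cycle midpoints)? Default `TRUE`.
#' @param beta_n_eff Effective sample size scaling the printed per-patient SD
#'   of beta survival parameters: sampling SD = printed SD / sqrt(n_eff).
#'   Default 100. This is a calibration knob; see the vignette.
#' @param normal_coverage,lognormal_coverage Central coverage assigned to
#'   printed low-high pairs when fitting normal (age) and lognormal (hazard
#'   ratio) distributions. Default 0.95.
#' @param use_hazard_ratio When a record carries both a printed
#'   alternative-arm survival and a hazard-ratio treatment effect, use the
#'   hazard-ratio imputation instead of the printed survival? Default `FALSE`
#'   (imputation applies only when the survival is genuinely missing).
#' @param hr_direction Fallback hazard-ratio direction for records whose
#'   treatment effect has no explicit direction; `NA` (the default) makes
#'   imputation an error until a direction is chosen.
#' @return A `model_config` list.
#' @export
model_config <- function(discount_rate = 0.015, cycle_length_weeks = 1,
                         max_age = 100, month_length_days = 30.44,
                         horizon_mode = c("max_age_cap", "life_table"),
                         life_table = NULL, half_cycle = TRUE,
                         beta_n_eff = 100, normal_coverage = 0.95,
                         lognormal_coverage = 0.95, use_hazard_ratio = FALSE,
                         hr_direction = NA_character_) {
  horizon_mode <- match.arg(horizon_mode)
  stopifnot(discount_rate >= 0, discount_rate < 1, cycle_length_weeks > 0,
            max_age > 0, max_age <= 100, month_length_days > 0, beta_n_eff > 0)
  if (horizon_mode == "life_table") {
    if (is.null(life_table)) stop("horizon_mode 'life_table' requires a life_table",
                                  call. = FALSE)
    life_table <- .check_life_table(life_table)
  }
  structure(list(discount_rate = discount_rate, cycle_length_weeks = cycle_length_weeks,
                 max_age = max_age, month_length_days = month_length_days,
                 horizon_mode = horizon_mode, life_table = life_table,
                 half_cycle = half_cycle, beta_n_eff = beta_n_eff,
                 normal_coverage = normal_coverage, lognormal_coverage = lognormal_coverage,
                 use_hazard_ratio = use_hazard_ratio, hr_direction = hr_direction),
            class = "model_config")
}

.check_life_table <- function(lt) {
  stopifnot(is.data.frame(lt),
            all(c("age_years", "annual_mortality_rate") %in% names(lt)))
  stopifnot(all(lt$annual_mortality_rate >= 0), !is.unsorted(lt$age_years))
  lt
}

#' Load a life table from CSV
#'
#' @param path CSV with columns `age_years`, `annual_mortality_rate` (annual
#'   all-cause hazard); rates are linearly interpolated between tabulated ages
#'   and held constant beyond the table's range.
#' @return A validated life-table data frame.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  .check_life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Synthetic Gompertz-Makeham life table
#'
#' Builds a synthetic all-cause mortality table of the Gompertz-Makeham form
#' `rate(age) = makeham + a * exp(b * age)`, with defaults chosen to
#' approximate contemporary Western-European mortality (about 0.3% at age 30,
#' 1.2% at 68, 4% at 80, 11% at 90). It stands in for a national life table,
#' which the package does not ship; substitute a real table via
#' [load_life_table()] to tailor the background mortality.
#'
#' @param max_age Last tabulated age (default 110).
#' @param makeham Age-independent hazard component (default 5e-4).
#' @param a,b Gompertz scale and log-slope (defaults 9e-6 and 0.105).
#' @return A life-table data frame.
#' @export
synthetic_life_table <- function(max_age = 110, makeham = 5e-4, a = 9e-6, b = 0.105) {
  age <- 0:max_age
  data.frame(age_years = age, annual_mortality_rate = makeham + a * exp(b * age))
}

#' Reference model configuration
#'
#' The configuration committed as the package's reference for reproducing the
#' registry-wide results: life-table horizon mode with the packaged synthetic
#' Gompertz-Makeham background mortality, weekly cycles, 1.5% discounting,
#' `beta_n_eff = 100`, and a 30.44-day month. See the vignette for how each
#' knob was fixed.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
reference_config <- function(...) {
  model_config(horizon_mode = "life_table", life_table = synthetic_life_table(), ...)
}

WEEKS_PER_YEAR <- 365.25 / 7

#' Build the grid of delay scenarios
#'
#' Arithmetic grid of weeks-to-surgery, inclusive of the start (and of the end
#' when it lies on the grid), optionally appending permanent postponement
#' (`Inf`: the cohort never transitions to surgery).
#'
#' @param start_weeks,step_weeks,end_weeks Grid definition (defaults 2, 10,
#'   52: scenarios 2, 12, ..., 52 weeks; a 2-week delay is read as direct
#'   surgery).
#' @param include_permanent Append `Inf`? Default `FALSE`.
#' @return Numeric vector of delays in weeks.
#' @examples
#' build_delay_grid() # 2 12 22 32 42 52
#' @export
build_delay_grid <- function(start_weeks = 2, step_weeks = 10, end_weeks = 52,
                             include_permanent = FALSE) {
  stopifnot(start_weeks <= end_weeks, step_weeks > 0, start_weeks >= 2)
  g <- seq(start_weeks, end_weeks, by = step_weeks)
  if (include_permanent) g <- c(g, Inf)
  g
}

# Occupancy and reward core shared by run_cohort() and the PSA fast path.
# States: alternative (1), surgery (2), deceased. The cohort starts fully in
# the alternative state; survivors transition to surgery at the delay
# boundary; under permanent postponement they never do. Background mortality
# (life-table mode) adds to both arms' hazards.
.cohort_core <- function(u_alt, u_surg, lambda_alt, lambda_surg, age,
                         delay_weeks, config) {
  dt <- config$cycle_length_weeks / WEEKS_PER_YEAR
  n <- max(0L, as.integer(round((config$max_age - age) / dt)))
  if (n == 0L) {
    return(list(time = 0, alt = 1, surg = 0, increments = numeric(), qalys = 0))
  }
  t <- (0:n) * dt
  d_idx <- if (is.infinite(delay_weeks)) n else
    min(n, as.integer(round(delay_weeks / config$cycle_length_weeks)))
  t_d <- d_idx * dt
  if (config$horizon_mode == "life_table") {
    lt <- config$life_table
    mu <- stats::approx(lt$age_years, lt$annual_mortality_rate,
                        xout = age + t[-1] - dt / 2, rule = 2)$y
    cum_mu <- c(0, cumsum(mu * dt))
  } else {
    cum_mu <- 0
  }
  alive <- exp(-lambda_alt * pmin(t, t_d) - lambda_surg * pmax(t - t_d, 0) - cum_mu)
  in_alt <- (0:n) <= d_idx
  alt <- ifelse(in_alt, alive, 0)
  surg <- alive - alt
  r <- config$discount_rate
  head_ <- function(x) x[-(n + 1L)]
  tail_ <- function(x) x[-1L]
  if (config$half_cycle) {
    v <- exp(-r * (tail_(t) - dt / 2))
    inc <- dt * v * (u_alt * (head_(alt) + tail_(alt)) / 2 +
                       u_surg * (head_(surg) + tail_(surg)) / 2)
  } else {
    v <- exp(-r * head_(t))
    inc <- dt * v * (u_alt * head_(alt) + u_surg * head_(surg))
  }
  list(time = t, alt = alt, surg = surg, increments = inc, qalys = sum(inc))
}

#' Simulate the three-state cohort for one delay scenario
#'
#' The entire cohort starts in the alternative-treatment state and dies at the
#' alternative-arm hazard; at the delay boundary the survivors transition to
#' the surgery state and die at the surgery-arm hazard; under permanent
#' postponement (`delay_weeks = Inf`) they remain in the alternative state
#' until death. Simulation runs to `max_age`; in life-table mode the
#' age-specific background hazard is added to both arms.
#'
#' @param params List with elements `u_alt`, `u_surg` (utilities in \[0, 1\]),
#'   `lambda_alt`, `lambda_surg` (annual hazards), `age` (years at start).
#' @param delay_weeks Weeks to surgery (>= 2), or `Inf` for permanent
#'   postponement.
#' @param config A [model_config()].
#' @return A `cohort_trace` data frame with per-cycle-boundary columns `time`
#'   (years), `alternative`, `surgery`, `deceased` (occupancies summing to 1)
#'   and, as an attribute, the per-cycle discounted utility increments.
#' @export
run_cohort <- function(params, delay_weeks, config = model_config()) {
  stopifnot(params$u_alt >= 0, params$u_alt <= 1, params$u_surg >= 0, params$u_surg <= 1,
            params$lambda_alt >= 0, params$lambda_surg >= 0,
            params$age >= 0, params$age < config$max_age,
            is.infinite(delay_weeks) || delay_weeks >= 2)
  core <- .cohort_core(params$u_alt, params$u_surg, params$lambda_alt,
                       params$lambda_surg, params$age, delay_weeks, config)
  trace <- data.frame(time = core$time, alternative = core$alt, surgery = core$surg,
                      deceased = 1 - core$alt - core$surg)
  attr(trace, "increments") <- core$increments
  attr(trace, "qalys") <- core$qalys
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' Sums the per-cycle discounted utility increments of the trace: occupancy
#' times state utility times cycle length, discounted continuously at the
#' configured annual rate (trapezoidal occupancy at cycle midpoints under the
#' half-cycle correction).
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return Discounted QALYs (years).
#' @export
discounted_qalys <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  attr(trace, "qalys")
}

#' Closed-form discounted QALYs under constant hazards
#'
#' Continuous-time solution used as an analytic oracle for the cohort
#' simulation (valid in `max_age_cap` mode):
#' `u_alt * A(lambda_alt + r, D) + exp(-(lambda_alt + r) * D) * u_surg *
#' A(lambda_surg + r, T - D)` with `A(a, t) = (1 - exp(-a t)) / a` (and the
#' limit `A(0, t) = t`), `D` the delay and `T` the horizon, both in years.
#'
#' @param u_alt,u_surg Utilities.
#' @param lambda_alt,lambda_surg Annual hazards.
#' @param r Annual discount rate.
#' @param delay_years Delay `D` in years.
#' @param horizon_years Horizon `T` in years (`delay_years <= horizon_years`).
#' @return Discounted QALYs (years).
#' @export
closed_form_qaly <- function(u_alt, u_surg, lambda_alt, lambda_surg, r,
                             delay_years, horizon_years) {
  stopifnot(delay_years >= 0, horizon_years >= delay_years)
  ann <- function(a, t) ifelse(abs(a) < 1e-12, t, -expm1(-a * t) / a)
  a1 <- lambda_alt + r
  a2 <- lambda_surg + r
  u_alt * ann(a1, delay_years) +
    exp(-a1 * delay_years) * u_surg * ann(a2, horizon_years - delay_years)
}

#' Resolve a comparison record to point values
#'
#' Converts the record's central estimates to the reals the engine consumes:
#' utilities (triangular modes as printed), annual hazards from the horizon
#' survival probabilities, and the mean age. A missing alternative-arm
#' survival is imputed from the hazard-ratio treatment effect (see
#' [impute_missing_survival()]); with `config$use_hazard_ratio = TRUE` the
#' imputation is used even when a printed survival exists.
#'
#' @param record A [comparison_record()].
#' @param config A [model_config()].
#' @return List with `u_alt`, `u_surg`, `lambda_alt`, `lambda_surg`, `age`.
#' @export
resolve_point_values <- function(record, config = model_config()) {
  sa <- record$surv_altern
  use_hr <- (is.null(sa) || isTRUE(config$use_hazard_ratio)) && !is.null(record$tx_eff)
  if (is.null(sa) && !use_hr) {
    stop("record ", record_key(record),
         " has neither an alternative-arm survival nor a treatment effect", call. = FALSE)
  }
  if (use_hr) {
    eff <- record$tx_eff
    if (is.na(eff$direction) && !is.na(config$hr_direction)) eff$direction <- config$hr_direction
    sa <- impute_missing_survival(record$surv_surg, eff,
                                  target_horizon = record$surv_surg$horizon_years)
  }
  list(u_alt = record$qol_altern$mode, u_surg = record$qol_surg$mode,
       lambda_alt = hazard_from_survival(sa),
       lambda_surg = hazard_from_survival(record$surv_surg),
       age = record$age$mean_years)
}

# QALYs for a vector of delays at given point values (PSA fast path)
.qalys_for_delays <- function(vals, delays_weeks, config) {
  vapply(delays_weeks, function(d) {
    .cohort_core(vals$u_alt, vals$u_surg, vals$lambda_alt, vals$lambda_surg,
                 vals$age, d, config)$qalys
  }, numeric(1))
}

#' DALYs per month of surgical delay at point estimates
#'
#' Runs the cohort at a 2-week delay (read as direct surgery) and at a
#' 52-week delay, takes the discounted-QALY difference -- the health effect of
#' a 50-week delay -- and expresses it per month. Surgery is the reference:
#' identical arms give exactly zero; a positive value is the health loss from
#' substituting surgery with the alternative, a negative value a health gain.
#'
#' @param record A [comparison_record()], or a resolved value list as returned
#'   by [resolve_point_values()].
#' @param config A [model_config()].
#' @param reference_weeks,delay_weeks The two delays compared (defaults 2
#'   and 52).
#' @return A `point_outcome` list with `discounted_qalys` (named pair) and
#'   `dalys_per_month`.
#' @export
dalys_per_month <- function(record, config = model_config(),
                            reference_weeks = 2, delay_weeks = 52) {
  vals <- if (inherits(record, "comparison_record"))
    resolve_point_values(record, config) else record
  q <- .qalys_for_delays(vals, c(reference_weeks, delay_weeks), config)
  months <- (delay_weeks - reference_weeks) * 7 / config$month_length_days
  structure(list(discounted_qalys = stats::setNames(q, c("reference", "delayed")),
                 dalys_per_month = (q[[1]] - q[[2]]) / months),
            class = "point_outcome")
}
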