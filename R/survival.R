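#' Constant hazard from a horizon survival probability
#'
#' Under the exponential (constant-hazard) assumption, a probability `S` of
#' surviving `k` years implies an annual hazard `-log(S) / k`. This is the
#' structural assumption used to extrapolate a single printed k-year survival
#' over the cohort's remaining lifetime; no other survival shape is modelled.
#'
#' @param estimate A [survival_estimate()], or a bare probability (with
#'   `horizon_years` then supplied separately).
#' @param horizon_years Horizon in years when `estimate` is a bare number.
#' @return Annual hazard rate (nonnegative scalar).
#' @examples
#' hazard_from_survival(survival_estimate(0.842, 5))  # multivessel OMT arm
#' @export
hazard_from_survival <- function(estimate, horizon_years = NULL) {
  if (inherits(estimate, "survival_estimate")) {
    p <- estimate$probability
    k <- estimate$horizon_years
  } else {
    p <- estimate
    k <- horizon_years
  }
  stopifnot(is.numeric(p), length(p) == length(k) || length(k) == 1L, all(k > 0))
  if (any(p <= 0)) stop("survival probability 0 implies an infinite hazard", call. = FALSE)
  if (any(p > 1)) stop("survival probability above 1", call. = FALSE)
  -log(p) / k
}

#' Survival probability at a horizon under a constant hazard
#'
#' @param rate Annual hazard rate.
#' @param horizon_years Horizon in years.
#' @return `exp(-rate * horizon_years)`.
#' @export
survival_at <- function(rate, horizon_years) {
  stopifnot(all(rate >= 0), all(horizon_years >= 0))
  exp(-rate * horizon_years)
}

#' Impute a missing survival arm from a hazard-ratio treatment effect
#'
#' Proportional hazards under the exponential assumption: the missing arm's
#' hazard is the known arm's hazard multiplied (or divided) by the hazard
#' ratio, and its survival at `target_horizon` is `exp(-hazard * horizon)` --
#' equivalently the power rule `S_missing = S_known^(HR)` at equal horizons.
#' A known survival of 1 (zero hazard) is invariant under any hazard ratio.
#'
#' @param known [survival_estimate()] of the arm with data.
#' @param effect [treatment_effect()]; its `direction` must be set: with the
#'   known arm being surgery, `"alternative_vs_surgery"` multiplies the known
#'   hazard by the ratio to obtain the alternative arm's hazard, and
#'   `"surgery_vs_alternative"` divides.
#' @param target_horizon Horizon (years) at which the imputed probability is
#'   expressed.
#' @param hazard_ratio Optional sampled ratio overriding the point estimate
#'   (used per PSA iteration).
#' @return A degenerate [survival_estimate()] at `target_horizon`.
#' @export
impute_missing_survival <- function(known, effect, target_horizon,
                                    hazard_ratio = NULL) {
  stopifnot(inherits(known, "survival_estimate"), inherits(effect, "treatment_effect"),
            target_horizon > 0)
  if (is.na(effect$direction)) {
    stop("treatment-effect direction is not set; specify 'alternative_vs_surgery' ",
         "or 'surgery_vs_alternative' explicitly (the source tables do not state ",
         "the reference arm)", call. = FALSE)
  }
  hr <- if (is.null(hazard_ratio)) effect$hazard_ratio else hazard_ratio
  stopifnot(hr > 0)
  h_known <- hazard_from_survival(known)
  h_missing <- switch(effect$direction,
                      alternative_vs_surgery = h_known * hr,
                      surgery_vs_alternative = h_known / hr)
  survival_estimate(probability = survival_at(h_missing, target_horizon),
                    horizon_years = target_horizon, family = "degenerate")
}
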