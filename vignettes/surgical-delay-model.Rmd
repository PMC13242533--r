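---
title: "A cohort model for the health effects of substituting surgery during delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort model for the health effects of substituting surgery during delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgdelay)
```

## The question the model answers

Scarce surgical capacity forces a choice: which surgeries should keep their
slot, and which can be delayed while the patient receives a nonsurgical
alternative treatment? `surgdelay` frames the answer in health terms: for
each disease–surgery–alternative combination it estimates the
disability-adjusted life-years (DALYs) lost — or gained — per month that the
surgery is delayed and the alternative given instead. Ranking each
disease–surgery pair by the DALYs of its *best* alternative (the one losing
the least health) yields a utilitarian prioritization: the surgery whose best
substitute loses the most health per month is the one to protect first.

## Model structure and assumptions

The model is a three-state cohort state-transition model: *alternative
treatment*, *surgery*, *deceased*. The cohort enters at its mean treatment
age, entirely in the alternative-treatment state, and experiences a constant
annual mortality hazard $\lambda_{alt}$ there. At the delay boundary $D$
(weeks) all survivors transition to the surgery state, where the hazard is
$\lambda_{surg}$; under permanent postponement ($D = \infty$) they remain in
the alternative state until death. Both treated states carry a utility
$u \in [0,1]$ from their first cycle onward. Structural assumptions, all
deliberate simplifications:

* **Exponential survival.** Each arm's evidence is a single probability of
  surviving a stated horizon ($k$-year survival $S$); the constant hazard
  $\lambda = -\ln(S)/k$ is the minimal extrapolation of that one number over
  the remaining lifetime. No time-varying hazards or cure fractions.
* **Immediate, lasting treatment effect.** Utilities apply from the first
  cycle in a state; treatment duration and the temporarily reduced quality of
  life during recovery are not modelled.
* **Proportional hazards for imputation.** When one arm's survival is
  missing, a hazard-ratio treatment effect converts the known arm's hazard
  ($\lambda_{missing} = HR \cdot \lambda_{known}$, equivalently
  $S_{missing} = S_{known}^{HR}$ at equal horizons). The evidence tables do
  not state the ratio's reference arm, so `impute_missing_survival()` refuses
  to run until a direction is set explicitly. Two registry records (the
  breast-cancer chemotherapy + immunotherapy rows) carry *both* a printed
  alternative-arm survival and a hazard ratio; the printed survival is used
  and the ratio ignored unless `model_config(use_hazard_ratio = TRUE)`,
  because imputation is a fallback for missing data, not a substitute for it.
* **No queue dynamics, costs or equity weights.** The model compares two
  fixed delay scenarios; capacity, waiting-list feedback and resource costs
  are out of scope.

Health outcomes are discounted quality-adjusted life-years. For constant
hazards the continuous-time value has the closed form

$$Q(D) = u_{alt}\,A(\lambda_{alt}+r, D) + e^{-(\lambda_{alt}+r)D}\,
u_{surg}\,A(\lambda_{surg}+r, T-D), \qquad A(a,t) = \frac{1-e^{-at}}{a},$$

with $r$ the discount rate and $T$ the horizon. The engine itself is a
discrete weekly-cycle simulation (so that background mortality can vary with
age), and `closed_form_qaly()` serves as its independent analytic oracle: at
weekly cycles the two agree to well under 0.5% relative error.

The outcome is anchored to direct surgery: a 2-week delay is read as
immediate surgery, and

$$\text{DALYs/month} = \frac{Q(2\,\text{wk}) - Q(52\,\text{wk})}
{11.50\ \text{months}},$$

so identical arms give exactly zero, a worse alternative a positive health
loss, a better alternative a negative value (a health gain).

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| `discount_rate` | 0.015 /y | Dutch guideline rate for health effects; applied continuously, $e^{-rt}$, matching the analytic oracle (the difference from annual compounding is < 0.01%). |
| `cycle_length_weeks` | 1 | The delay grid (2, 12, …, 52 weeks) lands exactly on cycle boundaries. |
| `max_age` | 100 y | Hard ceiling on the simulated lifespan. |
| `month_length_days` | 30.44 | 365.25/12; a 50-week delay is 11.50 months. |
| `half_cycle` | TRUE | Trapezoidal occupancy with midpoint discounting; second-order accurate in the cycle length. |
| `beta_n_eff` | 100 | See below. |
| `normal_coverage`, `lognormal_coverage` | 0.95 | Printed low–high pairs are read as central 95% intervals. |

Three printed-table ambiguities required a reading, fixed once:

* **Beta spreads (`beta_n_eff`).** The registry prints survival
  probabilities with an "SD" near $\sqrt{p(1-p)}$ — a per-patient Bernoulli
  SD, not the standard error of the estimate. Used raw it yields U-shaped
  beta distributions incompatible with the narrow intervals the same sources
  report. The sampler therefore uses $sd/\sqrt{n_{eff}}$ with a configurable
  effective sample size, default 100 — the order of magnitude of the underlying
  study arms. This is the model's most prominent calibration knob and is
  recorded in every run manifest.
* **Triangular survivals and utilities.** Values printed as a central value
  with a low–high range are taken as the triangular *mode* with the printed
  bounds. Sampled triangular means therefore differ from the printed central
  values (mean = (low + mode + high)/3), which is visible in skewed rows.
* **Ages.** Printed mean with low–high, read as normal with the pair as a
  95% interval, truncated to [0, 100].

Out-of-support draws are resampled (up to 100 rounds) and then clipped — the
mean stays close to its analytic value while probabilities, utilities, ages
and hazard ratios stay in range. Spreads below $10^{-8}$ collapse to a
degenerate atom. Every parameter of every record draws from its own
substream, derived by stably hashing the record key and parameter name with
the master seed: reproducible, and independent of evaluation order.

## Horizon modes and the reference configuration

The evidence gives only "a maximum age of 100"; whether general-population
mortality ran underneath the disease hazards is a genuinely open structural
choice, so the package provides both modes and reports the difference rather
than hiding it:

* `max_age_cap` (default): only the disease hazards act; everyone alive at
  100 dies there.
* `life_table`: an age-specific background hazard is added to both arms.

Under `max_age_cap` the model's point estimates overshoot the magnitudes the
evidence base reports for the high-mortality cardiac records (e.g. the
pacemaker substitution comes out near 0.17 DALYs/month at point estimates),
because a 68-year-old surgical cohort is credited with up to 32 background-
mortality-free years. Layering background mortality brings the magnitudes in
line, which is why the committed `reference_config()` uses `life_table` mode.
Since no national life table can be shipped, the package generates a
**synthetic** Gompertz–Makeham table,
$\mu(x) = 5\times10^{-4} + 9\times10^{-6} e^{0.105x}$, chosen to approximate
contemporary Western-European all-cause mortality (≈0.3% at 30, 1.2% at 68,
4% at 80, 11% at 90) — `synthetic_life_table()`. Substituting a real table
via `load_life_table()` is a one-line change. The remaining reference
settings are the defaults above; together with the seed they fully determine
a run, and `cmd_run()` writes them into its manifest.

## Probabilistic sensitivity analysis and ranking

`run_psa()` repeats the model (default 1,000 iterations), sampling every
uncertain parameter per iteration — including age, so the horizon varies
across iterations — and summarizes DALYs/month as the mean with empirical
2.5/97.5 percentiles (the standard PSA interval choice; the interval is
reported as a 95% CI). Iterations that sample a survival of exactly zero are
discarded and counted; more than 5% aborts with diagnostics. `run_psa()` with
two different seeds agrees to within Monte-Carlo error; one source reports
slightly different interval bounds for the ICD record in two places
(0.05–0.10 vs 0.06–0.10), and the package simply reports its own percentiles.

`select_best_alternative()` takes, per disease–surgery pair, the alternative
with the lowest mean (ties break lexicographically on the label);
`rank_alternatives()` orders pairs by descending mean. With the packaged
registry and the reference configuration the ranking is headed by the
pacemaker and ICD substitutions and ends with the two laryngeal-cancer pairs,
whose alternatives are marginal health *gains* with intervals spanning zero.

## What the synthetic generator emulates — and what it does not

`make_null_record()` and `make_effect_record()` produce records with the same
schema and distribution families as the registry but with known ground truth:
identical arms (exact zero, zero-width PSA interval) or prescribed utility
and hazard gaps whose expected DALYs/month follow from `closed_form_qaly()`.
Synthetic utilities use symmetric triangular spreads so the sampled mean
equals the mode, decoupling engine tests from the mean-vs-mode reading above.
The generator emulates parameter *uncertainty*, not evidence pathology: no
between-study heterogeneity, no correlated parameters (the PSA samples
independently, as the analysis design specifies), no mis-specified horizons.
Passing tests on synthetic records validate the arithmetic of the pipeline,
not the clinical accuracy of any registry row.

## Numerical choices

* Horizon truncated to whole cycles: $N = \operatorname{round}((100 - a)/\Delta)$
  weekly cycles; oracle comparisons use the same truncated horizon.
* The transition happens at the delay boundary cycle; with the half-cycle
  correction, the transition cycle's utility is the average of the two
  states', the standard treatment.
* $A(a, t)$ is computed via `expm1` with the $a \to 0$ limit taken below
  $10^{-12}$, so zero hazards and zero discounting are exact.
* Test problem sizes: empirical-vs-analytic mean checks use $10^5$ draws
  (3-standard-error bands), the engine-vs-oracle sweep 100 random parameter
  sets, and the registry-wide reproduction one 1,000-iteration PSA — sizes at
  which Monte-Carlo error is well below the decision-relevant differences.

## Known limitations

The model inherits every limitation of its inputs: single-horizon survivals
stretched exponentially over decades, expert-elicited utilities on a VAS, and
evidence populations that only approximately match the modelled cohorts (the
registry's sources note, e.g., that the medical-therapy arm for bradycardia
comes from a more severely diseased population than its no-treatment
comparators). One registry inventory line counts 11 diseases where the
detailed tables enumerate 13 pairs; the package follows the tables. The
synthetic life table is a smooth stand-in, not a statistical office product —
infant and accident-hump mortality are absent, which is immaterial here
because background mortality only matters at the ages where the Gompertz term
dominates. Results are decision *aids* at the population level; none of this
supports individual treatment decisions.
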