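#' Distribution specifications for probabilistic sensitivity analysis
#'
#' A `dist_spec` captures one uncertain model input as a samplable
#' distribution: its family (`beta`, `triangular`, `normal`, `lognormal` or
#' `degenerate`), its family-specific shape parameters, and a closed support
#' interval to which draws are truncated (probabilities and utilities live in
#' \[0, 1\], ages in \[0, 100\], hazard ratios in (0, Inf)).
#'
#' @param family Character scalar, one of `"beta"`, `"triangular"`,
#'   `"normal"`, `"lognormal"`, `"degenerate"`.
#' @param params Named numeric vector of shape parameters.
#' @param support Numeric length-2 vector, the closed truncation interval.
#' @return An object of class `dist_spec`.
#' @keywords internal
new_dist_spec <- function(family, params, support = c(-Inf, Inf)) {
  stopifnot(family %in% c("beta", "triangular", "normal", "lognormal", "degenerate"),
            is.numeric(params), length(support) == 2L, support[1] <= support[2])
  structure(list(family = family, params = params, support = as.numeric(support)),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s: %s; support [%g, %g]>\n", x$family,
              paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
              x$support[1], x$support[2]))
  invisible(x)
}

# below this spread the distribution is collapsed to its atom: sampling a
# near-zero-variance beta/normal is numerically pointless and the registry
# prints several exact-1 survivals with no spread at all
.SPREAD_EPS <- 1e-8

#' Beta shape parameters from a mean and an effective standard deviation
#'
#' Method-of-moments fit: with `nu = mean * (1 - mean) / sd^2 - 1`, the shapes
#' are `(mean * nu, (1 - mean) * nu)`, so the fitted distribution has exactly
#' the requested mean. Spreads below a numerical threshold collapse to a
#' degenerate atom at the mean (the vanishing-variance limit).
#'
#' The printed dispersion of a registry survival probability is a per-patient
#' (Bernoulli-scale) SD near `sqrt(p * (1 - p))`; used raw it would imply a
#' U-shaped beta. [beta_spec()] therefore divides it by `sqrt(n_eff)` before
#' calling this function; see the package vignette for the calibration.
#'
#' @param mean Mean in (0, 1).
#' @param sd_effective Standard deviation of the fitted beta, positive.
#' @return Numeric `c(shape1, shape2)`, or `NULL` when the spread is below the
#'   degenerate threshold.
#' @examples
#' beta_shapes_from_moments(0.5, sqrt(1 / 12)) # uniform: (1, 1)
#' @export
beta_shapes_from_moments <- function(mean, sd_effective) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean > 0, mean < 1,
            is.numeric(sd_effective), length(sd_effective) == 1L, sd_effective >= 0)
  if (sd_effective < .SPREAD_EPS) return(NULL)
  v <- sd_effective^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(paste("infeasible beta moments: sd^2 = %.4g >= mean*(1-mean) = %.4g;",
                       "increase the effective sample size (beta_n_eff) used to scale",
                       "the printed SD"), v, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Beta specification for a survival probability
#'
#' @param mean Mean probability in (0, 1); exactly 0 or 1 gives a degenerate
#'   atom.
#' @param sd Printed (per-patient scale) standard deviation.
#' @param n_eff Effective sample size dividing `sd^2`; `sd_effective =
#'   sd / sqrt(n_eff)`.
#' @return A `dist_spec`.
#' @export
beta_spec <- function(mean, sd, n_eff = 100) {
  stopifnot(mean >= 0, mean <= 1, n_eff > 0)
  if (mean <= 0 || mean >= 1) return(degenerate_spec(mean))
  shapes <- beta_shapes_from_moments(mean, sd / sqrt(n_eff))
  if (is.null(shapes)) return(degenerate_spec(mean))
  new_dist_spec("beta", shapes, support = c(0, 1))
}

#' Triangular specification
#'
#' Standard triangular distribution on `[low, high]` with apex at `mode`.
#' A collapsed interval (`low == high`) gives a degenerate atom. The analytic
#' mean is `(low + mode + high) / 3`.
#'
#' @param low,mode,high Reals with `low <= mode <= high`.
#' @return A `dist_spec`.
#' @examples
#' triangular_spec(0.3, 0.675, 0.85)
#' @export
triangular_spec <- function(low, mode, high) {
  if (!(low <= mode && mode <= high)) {
    stop(sprintf("triangular ordering violated: low=%g, mode=%g, high=%g", low, mode, high),
         call. = FALSE)
  }
  if (high - low < .SPREAD_EPS) return(degenerate_spec(mode))
  new_dist_spec("triangular", c(low = low, mode = mode, high = high),
                support = c(low, high))
}

#' Normal specification from a mean and a coverage interval
#'
#' The printed `low`--`high` pair is read as a central `coverage` interval, so
#' `sd = (high - low) / (2 * qnorm((1 + coverage) / 2))`.
#'
#' @param mean Mean.
#' @param low,high Interval endpoints, `low <= mean <= high`.
#' @param coverage Central coverage of the printed interval (default 0.95).
#' @param support Truncation interval for draws (ages use `[0, 100]`).
#' @return A `dist_spec`.
#' @export
normal_spec <- function(mean, low, high, coverage = 0.95, support = c(-Inf, Inf)) {
  stopifnot(low <= mean, mean <= high, coverage > 0, coverage < 1)
  if (high - low < .SPREAD_EPS) return(degenerate_spec(mean))
  sd <- (high - low) / (2 * stats::qnorm((1 + coverage) / 2))
  new_dist_spec("normal", c(mean = mean, sd = sd), support = support)
}

#' Lognormal specification from a point estimate and bounds
#'
#' Location is `log(point)` (the distribution's median equals `point`); the
#' log-scale SD is `(log(high) - log(low)) / (2 * z)` with `z` the standard
#' normal quantile of `(1 + coverage) / 2`.
#'
#' @param point Positive point estimate (median of the fitted distribution).
#' @param low,high Positive bounds with `low <= point <= high`.
#' @param coverage Central coverage of the bounds (default 0.95).
#' @return A `dist_spec`.
#' @examples
#' lognormal_spec_from_bounds(0.66, 0.65, 0.72)
#' @export
lognormal_spec_from_bounds <- function(point, low, high, coverage = 0.95) {
  if (min(point, low, high) <= 0) stop("lognormal bounds must be positive", call. = FALSE)
  stopifnot(low <= point, point <= high, coverage > 0, coverage < 1)
  if (high - low < .SPREAD_EPS) return(degenerate_spec(point))
  sdlog <- (log(high) - log(low)) / (2 * stats::qnorm((1 + coverage) / 2))
  new_dist_spec("lognormal", c(meanlog = log(point), sdlog = sdlog),
                support = c(0, Inf))
}

#' Degenerate (point-mass) specification
#'
#' @param atom The single supported value.
#' @return A `dist_spec`.
#' @export
degenerate_spec <- function(atom) {
  new_dist_spec("degenerate", c(atom = atom), support = c(atom, atom))
}

#' Analytic mean of a distribution specification
#'
#' @param spec A `dist_spec`.
#' @return The mean of the (untruncated) distribution; for lognormal,
#'   `exp(meanlog + sdlog^2 / 2)`.
#' @export
spec_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
         degenerate = unname(p["atom"]),
         beta       = unname(p["shape1"] / (p["shape1"] + p["shape2"])),
         triangular = unname((p["low"] + p["mode"] + p["high"]) / 3),
         normal     = unname(p["mean"]),
         lognormal  = unname(exp(p["meanlog"] + p["sdlog"]^2 / 2)))
}

#' Derive a reproducible substream seed from a master seed and labels
#'
#' Each uncertain parameter of each disease-surgery-alternative record draws
#' from its own substream, derived by stably hashing the labels together with
#' the master seed. Sampling one parameter therefore never perturbs another's
#' draws, and results do not depend on evaluation order.
#'
#' @param master_seed Integer master seed.
#' @param ... Character labels identifying the substream (record key and
#'   parameter name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "\r")
  m <- 2147483647 # 2^31 - 1, prime; doubles stay exact (< 2^53) throughout
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(h)
}

#' Draw seeded samples from a distribution specification
#'
#' Draws are truncated to the spec's support by resampling out-of-support
#' values (up to 100 rounds) and clipping any stragglers, which keeps the
#' empirical mean close to the analytic mean while guaranteeing support.
#' The global RNG state is restored on exit.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @param seed Integer substream seed (see [substream_seed()]); `NULL` uses
#'   the current RNG state.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (spec$family == "degenerate") return(rep(unname(spec$params["atom"]), n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  draw <- function(k) {
    p <- spec$params
    switch(spec$family,
           beta       = stats::rbeta(k, p["shape1"], p["shape2"]),
           triangular = .rtriangular(k, p["low"], p["mode"], p["high"]),
           normal     = stats::rnorm(k, p["mean"], p["sd"]),
           lognormal  = stats::rlnorm(k, p["meanlog"], p["sdlog"]))
  }
  x <- draw(n)
  lo <- spec$support[1]; hi <- spec$support[2]
  for (i in seq_len(100)) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- draw(length(bad))
  }
  pmin(pmax(x, lo), hi)
}

# inverse-CDF triangular sampler
.rtriangular <- function(n, low, mode, high) {
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}
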