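#' Distribution specifications for one record's uncertain parameters
#'
#' Maps each printed estimate to its sampling distribution: survival
#' probabilities to beta (method-of-moments on the printed SD scaled by
#' `beta_n_eff`) or triangular (printed value as mode), utilities to
#' triangular, age to a truncated normal (printed low-high read as a 95%
#' interval, support \[0, `max_age`\]), and the hazard ratio to lognormal with
#' median at the printed point.
#'
#' @param record A [comparison_record()].
#' @param config A [model_config()].
#' @return Named list of [new_dist_spec()] objects (entries absent when the
#'   record lacks the parameter).
#' @export
record_specs <- function(record, config = model_config()) {
  surv_to_spec <- function(est) {
    if (is.null(est)) return(NULL)
    switch(est$family,
           degenerate = degenerate_spec(est$probability),
           beta       = beta_spec(est$probability, est$sd, n_eff = config$beta_n_eff),
           triangular = triangular_spec(est$low, est$probability, est$high))
  }
  qol_to_spec <- function(est) triangular_spec(est$low, est$mode, est$high)
  specs <- list(
    surv_altern = surv_to_spec(record$surv_altern),
    surv_surg   = surv_to_spec(record$surv_surg),
    tx_eff      = if (!is.null(record$tx_eff))
      lognormal_spec_from_bounds(record$tx_eff$hazard_ratio, record$tx_eff$low,
                                 record$tx_eff$high,
                                 coverage = config$lognormal_coverage),
    qol_altern  = qol_to_spec(record$qol_altern),
    qol_surg    = qol_to_spec(record$qol_surg),
    age         = normal_spec(record$age$mean_years, record$age$low, record$age$high,
                              coverage = config$normal_coverage,
                              support = c(0, config$max_age)))
  specs[!vapply(specs, is.null, logical(1))]
}

.draw_record_params <- function(record, specs, n, seed) {
  key <- c(record$disease, record$surgery, record$alternative)
  out <- lapply(names(specs), function(par) {
    sample_dist(specs[[par]], n, seed = substream_seed(seed, key, par))
  })
  stats::setNames(out, names(specs))
}

#' Probabilistic sensitivity analysis for one comparison record
#'
#' For each iteration, samples every uncertain parameter from its distribution
#' (each from its own seeded substream, so results are reproducible and
#' independent of evaluation order), resolves survival probabilities to
#' constant hazards (imputing via the hazard ratio where the alternative-arm
#' survival is missing), runs the cohort at the 2- and 52-week delays, and
#' records the DALYs per month. Iterations whose sampled survival is exactly
#' zero (infinite hazard) are discarded and counted; more than 5% such
#' failures aborts with diagnostics.
#'
#' @param record A [comparison_record()].
#' @param config A [model_config()].
#' @param n_iterations Number of PSA iterations (default 1000).
#' @param seed Integer master seed.
#' @return An `outcome_summary`: labels, `mean_daly_per_month`, `ci_low` /
#'   `ci_high` (empirical 2.5 and 97.5 percentiles), `n_iterations`,
#'   `n_failed`, `seed`; the per-iteration draws are kept in the `draws`
#'   element.
#' @export
run_psa <- function(record, config = model_config(), n_iterations = 1000, seed = 1) {
  stopifnot(inherits(record, "comparison_record"), n_iterations >= 1)
  viol <- validate_record(record)
  if (nrow(viol)) {
    stop("invalid record ", record_key(record), ": ",
         paste(viol$rule, collapse = "; "), call. = FALSE)
  }
  specs <- record_specs(record, config)
  draws <- .draw_record_params(record, specs, n_iterations, seed)
  use_hr <- (is.null(record$surv_altern) || isTRUE(config$use_hazard_ratio)) &&
    !is.null(record$tx_eff)
  if (is.null(record$surv_altern) && is.null(record$tx_eff)) {
    stop("record ", record_key(record), " is not resolvable: no alternative-arm ",
         "survival and no treatment effect", call. = FALSE)
  }
  direction <- NA_character_
  if (use_hr) {
    direction <- record$tx_eff$direction
    if (is.na(direction)) direction <- config$hr_direction
    if (is.na(direction)) {
      stop("hazard-ratio imputation for ", record_key(record), " requires an explicit ",
           "direction ('alternative_vs_surgery' or 'surgery_vs_alternative')", call. = FALSE)
    }
  }
  months <- 50 * 7 / config$month_length_days
  daly <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_iterations)) {
    p_surg <- draws$surv_surg[i]
    if (p_surg <= 0) next
    lambda_surg <- -log(p_surg) / record$surv_surg$horizon_years
    if (use_hr) {
      hr <- draws$tx_eff[i]
      lambda_alt <- switch(direction,
                           alternative_vs_surgery = lambda_surg * hr,
                           surgery_vs_alternative = lambda_surg / hr)
    } else {
      p_alt <- draws$surv_altern[i]
      if (p_alt <= 0) next
      lambda_alt <- -log(p_alt) / record$surv_altern$horizon_years
    }
    vals <- list(u_alt = draws$qol_altern[i], u_surg = draws$qol_surg[i],
                 lambda_alt = lambda_alt, lambda_surg = lambda_surg,
                 age = min(draws$age[i], config$max_age))
    q <- .qalys_for_delays(vals, c(2, 52), config)
    daly[i] <- (q[1] - q[2]) / months
  }
  failed <- sum(is.na(daly))
  if (failed > 0.05 * n_iterations) {
    stop(sprintf("PSA for %s: %d of %d iterations failed (sampled survival 0)",
                 record_key(record), failed, n_iterations), call. = FALSE)
  }
  ok <- daly[!is.na(daly)]
  structure(list(disease = record$disease, surgery = record$surgery,
                 alternative = record$alternative,
                 mean_daly_per_month = mean(ok),
                 ci_low = unname(stats::quantile(ok, 0.025)),
                 ci_high = unname(stats::quantile(ok, 0.975)),
                 n_iterations = n_iterations, n_failed = failed, seed = seed,
                 draws = daly),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("%s | %s | %s: %.3f DALYs/month (95%% CI %.3f to %.3f; %d iterations)\n",
              x$disease, x$surgery, x$alternative, x$mean_daly_per_month,
              x$ci_low, x$ci_high, x$n_iterations))
  invisible(x)
}

.summary_row <- function(s) {
  data.frame(disease = s$disease, surgery = s$surgery, alternative = s$alternative,
             mean_daly_per_month = s$mean_daly_per_month,
             ci_low = s$ci_low, ci_high = s$ci_high,
             n_iterations = s$n_iterations, seed = s$seed)
}

#' Run the PSA over a whole registry
#'
#' @param registry A `comparison_registry`.
#' @param config A [model_config()].
#' @param n_iterations,seed As in [run_psa()].
#' @return A `psa_summary` list: `summaries` (data frame, one row per
#'   combination), `grand_mean` (mean of the per-combination means),
#'   `failures` (named list of per-record errors, collected rather than
#'   fatal), and `outcomes` (the individual `outcome_summary` objects).
#' @export
summarize_all <- function(registry, config = model_config(), n_iterations = 1000,
                          seed = 1) {
  if (!length(registry)) {
    warning("empty registry: nothing to summarize")
    return(structure(list(summaries = data.frame(), grand_mean = NA_real_,
                          failures = list(), outcomes = list()),
                     class = "psa_summary"))
  }
  outcomes <- list(); failures <- list()
  for (rec in registry) {
    res <- tryCatch(run_psa(rec, config, n_iterations, seed),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[record_key(rec)]] <- conditionMessage(res)
    else outcomes[[record_key(rec)]] <- res
  }
  summaries <- do.call(rbind, lapply(outcomes, .summary_row))
  rownames(summaries) <- NULL
  structure(list(summaries = summaries,
                 grand_mean = mean(summaries$mean_daly_per_month),
                 failures = failures, outcomes = outcomes),
            class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary: %d combinations; grand mean %.3f DALYs/month>\n",
              nrow(x$summaries), x$grand_mean))
  print(x$summaries, digits = 3)
  if (length(x$failures)) {
    cat("failed records:\n")
    for (k in names(x$failures)) cat("  -", k, ":", x$failures[[k]], "\n")
  }
  invisible(x)
}

#' Best alternative for one disease-surgery pair
#'
#' The alternative with the lowest mean DALYs per month minimizes the health
#' loss of substituting the surgery; ties break lexicographically on the
#' alternative label.
#'
#' @param summaries Data frame of outcome summaries (rows of one
#'   disease-surgery pair).
#' @return The selected row.
#' @export
select_best_alternative <- function(summaries) {
  if (!nrow(summaries)) stop("no summaries to select from", call. = FALSE)
  if (nrow(unique(summaries[c("disease", "surgery")])) != 1L)
    stop("summaries span more than one disease-surgery pair", call. = FALSE)
  ord <- order(summaries$mean_daly_per_month, summaries$alternative)
  summaries[ord[1], , drop = FALSE]
}

#' Prioritization ranking of disease-surgery pairs
#'
#' Selects each disease-surgery pair's best alternative and orders the pairs
#' in descending mean DALYs per month: the pair at the top loses the most
#' health per month when its surgery is substituted, so its surgery is the one
#' to prioritize.
#'
#' @param summaries Data frame of outcome summaries over one or more pairs
#'   (e.g. the `summaries` element of [summarize_all()]), or a `psa_summary`.
#' @return A `ranking_table` data frame: one row per pair (its best
#'   alternative), descending by `mean_daly_per_month`, with `rank` and
#'   `best_flag` columns.
#' @export
rank_alternatives <- function(summaries) {
  if (inherits(summaries, "psa_summary")) summaries <- summaries$summaries
  if (!nrow(summaries)) stop("no summaries to rank", call. = FALSE)
  if (anyDuplicated(summaries[c("disease", "surgery", "alternative")]))
    stop("duplicate disease-surgery-alternative rows", call. = FALSE)
  pair <- paste(summaries$disease, summaries$surgery, sep = " | ")
  best <- do.call(rbind, lapply(split(summaries, pair), select_best_alternative))
  best <- best[order(-best$mean_daly_per_month, best$disease), , drop = FALSE]
  best$best_flag <- TRUE
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  class(best) <- c("ranking_table", "data.frame")
  best
}

#' Bar chart of the prioritization ranking
#'
#' Horizontal bars of mean DALYs per month with 95% percentile intervals, one
#' per disease-surgery pair (its best alternative), ordered by rank.
#'
#' @param ranking A `ranking_table` from [rank_alternatives()].
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ranking() requires the ggplot2 package", call. = FALSE)
  ranking$label <- sprintf("%s: %s (for %s)", ranking$disease,
                           ranking$alternative, ranking$surgery)
  ranking$label <- stats::reorder(ranking$label, -ranking$rank)
  ggplot2::ggplot(ranking, ggplot2::aes(x = mean_daly_per_month, y = label)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.25) +
    ggplot2::labs(x = "DALYs per month of delay", y = NULL) +
    ggplot2::theme_minimal()
}
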