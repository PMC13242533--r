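#' @title Parameter registry: disease-surgery-alternative comparison records
#' @description
#' Each record bundles the five model inputs for one
#' disease-surgery-alternative combination: survival probability of each arm
#' (a probability at a stated horizon), a utility (quality-of-life weight) for
#' each arm, the cohort's mean age, and optionally a hazard-ratio treatment
#' effect used to impute a missing survival arm. The registry shipped with the
#' package covers 13 disease-surgery pairs and 23 combinations.
#' @name registry
NULL

REGISTRY_COLUMNS <- c("disease", "surgery", "alternative", "parameter", "unit",
                      "mean", "spread_sd", "low", "high", "distribution", "source")
REGISTRY_PARAMETERS <- c("surv_altern", "surv_surg", "tx_eff",
                         "qol_altern", "qol_surg", "age")

#' Survival estimate: a probability of surviving to a stated horizon
#'
#' @param probability Survival fraction in \[0, 1\].
#' @param horizon_years Positive horizon (the k in "k-year survival").
#' @param sd Printed per-patient SD (beta rows), or `NA`.
#' @param low,high Printed bounds (triangular rows), or `NA`.
#' @param family `"beta"`, `"triangular"` or `"degenerate"`.
#' @return A `survival_estimate` list.
#' @export
survival_estimate <- function(probability, horizon_years, sd = NA_real_,
                              low = NA_real_, high = NA_real_,
                              family = c("beta", "triangular", "degenerate")) {
  family <- match.arg(family)
  structure(list(probability = probability, horizon_years = horizon_years,
                 sd = sd, low = low, high = high, family = family),
            class = "survival_estimate")
}

#' Utility (quality-of-life weight) estimate with triangular uncertainty
#'
#' @param mode Central utility in \[0, 1\] (the printed value, taken as the
#'   triangular mode).
#' @param low,high Printed bounds.
#' @return A `utility_estimate` list.
#' @export
utility_estimate <- function(mode, low, high) {
  structure(list(mode = mode, low = low, high = high, family = "triangular"),
            class = "utility_estimate")
}

#' Cohort mean-age estimate with normal uncertainty
#'
#' @param mean_years Mean age at treatment, years.
#' @param low,high Printed bounds, read as a central 95% interval.
#' @return An `age_estimate` list.
#' @export
age_estimate <- function(mean_years, low, high) {
  structure(list(mean_years = mean_years, low = low, high = high, family = "normal"),
            class = "age_estimate")
}

#' Hazard-ratio treatment effect with lognormal uncertainty
#'
#' @param hazard_ratio Positive point hazard ratio.
#' @param low,high Positive bounds.
#' @param direction Which arm the ratio multiplies:
#'   `"alternative_vs_surgery"` means the alternative arm's hazard equals the
#'   surgery arm's hazard times the ratio. The source tables do not state the
#'   reference arm, so imputation refuses to run until a direction is set
#'   explicitly (`NA` by default).
#' @return A `treatment_effect` list.
#' @export
treatment_effect <- function(hazard_ratio, low, high,
                             direction = NA_character_) {
  if (!is.na(direction)) {
    direction <- match.arg(direction, c("alternative_vs_surgery", "surgery_vs_alternative"))
  }
  structure(list(hazard_ratio = hazard_ratio, low = low, high = high,
                 family = "lognormal", direction = direction),
            class = "treatment_effect")
}

#' One disease-surgery-alternative comparison record
#'
#' @param disease,surgery,alternative Labels; the triple must be unique
#'   within a registry.
#' @param surv_surg Surgery-arm [survival_estimate()].
#' @param qol_altern,qol_surg [utility_estimate()]s for each arm.
#' @param age [age_estimate()].
#' @param surv_altern Alternative-arm [survival_estimate()], or `NULL` if it
#'   is to be imputed from `tx_eff`.
#' @param tx_eff Optional [treatment_effect()].
#' @param sources Free-text provenance.
#' @return A `comparison_record`.
#' @export
comparison_record <- function(disease, surgery, alternative,
                              surv_surg, qol_altern, qol_surg, age,
                              surv_altern = NULL, tx_eff = NULL, sources = "") {
  structure(list(disease = disease, surgery = surgery, alternative = alternative,
                 surv_altern = surv_altern, surv_surg = surv_surg, tx_eff = tx_eff,
                 qol_altern = qol_altern, qol_surg = qol_surg, age = age,
                 sources = sources),
            class = "comparison_record")
}

record_key <- function(record) {
  paste(record$disease, record$surgery, record$alternative, sep = " | ")
}

#' @export
print.comparison_record <- function(x, ...) {
  cat("<comparison_record>", record_key(x), "\n")
  invisible(x)
}

#' @export
print.comparison_registry <- function(x, ...) {
  cat(sprintf("<comparison_registry: %d combinations, %d disease-surgery pairs>\n",
              length(x), nrow(unique(data.frame(
                d = vapply(x, `[[`, "", "disease"),
                s = vapply(x, `[[`, "", "surgery"))))))
  for (r in x) cat("  -", record_key(r), "\n")
  invisible(x)
}

#' Validate one comparison record
#'
#' Checks every structural invariant: probabilities and utilities in \[0, 1\],
#' positive horizons, bound ordering (`low <= central <= high`), positive
#' hazard ratios, and the imputability rule that at least one of the
#' alternative-arm survival or the treatment effect is present. Violations are
#' returned as data, not thrown.
#'
#' @param record A [comparison_record()].
#' @return A data frame with columns `record`, `field`, `rule`; zero rows when
#'   the record is valid.
#' @export
validate_record <- function(record) {
  v <- list()
  key <- record_key(record)
  bad <- function(field, rule) {
    v[[length(v) + 1L]] <<- data.frame(record = key, field = field, rule = rule)
  }
  chk_surv <- function(est, field) {
    if (is.null(est)) return()
    if (!is.finite(est$probability) || est$probability < 0 || est$probability > 1)
      bad(field, "probability must be in [0, 1]")
    if (!is.finite(est$horizon_years) || est$horizon_years <= 0)
      bad(field, "horizon_years must be positive")
    if (est$family == "triangular" &&
        !(isTRUE(est$low <= est$probability) && isTRUE(est$probability <= est$high)))
      bad(field, "triangular bounds must satisfy low <= probability <= high")
    if (est$probability == 1 && est$family != "degenerate")
      bad(field, "probability 1 must be degenerate (no sampling)")
  }
  chk_qol <- function(est, field) {
    ok <- isTRUE(0 <= est$low) && isTRUE(est$low <= est$mode) &&
      isTRUE(est$mode <= est$high) && isTRUE(est$high <= 1)
    if (!ok) bad(field, "utility bounds must satisfy 0 <= low <= mode <= high <= 1")
  }
  chk_surv(record$surv_altern, "surv_altern")
  chk_surv(record$surv_surg, "surv_surg")
  chk_qol(record$qol_altern, "qol_altern")
  chk_qol(record$qol_surg, "qol_surg")
  a <- record$age
  if (!(isTRUE(a$low <= a$mean_years) && isTRUE(a$mean_years <= a$high)) ||
      !isTRUE(a$mean_years > 0))
    bad("age", "age bounds must satisfy low <= mean <= high with mean > 0")
  if (!is.null(record$tx_eff)) {
    t <- record$tx_eff
    if (!(isTRUE(0 < t$low) && isTRUE(t$low <= t$hazard_ratio) &&
          isTRUE(t$hazard_ratio <= t$high)))
      bad("tx_eff", "hazard ratio bounds must satisfy 0 < low <= HR <= high")
  }
  if (is.null(record$surv_altern) && is.null(record$tx_eff))
    bad("surv_altern", "at least one of surv_altern or tx_eff must be present")
  if (length(v)) do.call(rbind, v) else
    data.frame(record = character(), field = character(), rule = character())
}

.parse_horizon <- function(unit) {
  m <- regmatches(unit, regexpr("[0-9]+(\\.[0-9]+)?", unit))
  if (!length(m)) NA_real_ else as.numeric(m)
}

#' Load a parameter registry from CSV
#'
#' The file is long format, one row per parameter per combination, with
#' columns `disease, surgery, alternative, parameter, unit, mean, spread_sd,
#' low, high, distribution, source`. `parameter` is one of `surv_altern`,
#' `surv_surg`, `tx_eff`, `qol_altern`, `qol_surg`, `age`; survival units
#' carry the horizon as e.g. `"probability 5-y survival"`. Load order of the
#' combinations is preserved. Every record is validated; any violation aborts
#' with a message naming the record and field.
#'
#' @param path Path to the CSV file.
#' @param schema_version Schema label; only `"1"` is defined.
#' @return A `comparison_registry` (list of [comparison_record()]s).
#' @seealso [surgdelay_registry()] for the packaged registry,
#'   [write_registry()] for the inverse.
#' @export
load_registry <- function(path, schema_version = "1") {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  stopifnot(identical(schema_version, "1"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(df)) stop("registry schema error: file has no rows", call. = FALSE)
  bad_par <- setdiff(unique(df$parameter), REGISTRY_PARAMETERS)
  if (length(bad_par))
    stop("registry schema error: unknown parameter(s) ",
         paste(bad_par, collapse = ", "), call. = FALSE)

  key <- paste(df$disease, df$surgery, df$alternative, sep = " | ")
  records <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    get1 <- function(par) {
      r <- rows[rows$parameter == par, , drop = FALSE]
      if (nrow(r) > 1) stop("duplicate parameter '", par, "' for record ", k, call. = FALSE)
      if (nrow(r)) r else NULL
    }
    mk_surv <- function(r) {
      if (is.null(r)) return(NULL)
      survival_estimate(probability = r$mean, horizon_years = .parse_horizon(r$unit),
                        sd = r$spread_sd, low = r$low, high = r$high,
                        family = r$distribution)
    }
    mk_qol <- function(r) utility_estimate(mode = r$mean, low = r$low, high = r$high)
    sa <- get1("surv_altern"); ss <- get1("surv_surg"); tx <- get1("tx_eff")
    qa <- get1("qol_altern"); qs <- get1("qol_surg"); ag <- get1("age")
    for (req in list(c("surv_surg", is.null(ss)), c("qol_altern", is.null(qa)),
                     c("qol_surg", is.null(qs)), c("age", is.null(ag)))) {
      if (as.logical(req[2]))
        stop("registry schema error: record ", k, " lacks parameter ", req[1], call. = FALSE)
    }
    rec <- comparison_record(
      disease = rows$disease[1], surgery = rows$surgery[1], alternative = rows$alternative[1],
      surv_altern = mk_surv(sa), surv_surg = mk_surv(ss),
      tx_eff = if (!is.null(tx))
        treatment_effect(tx$mean, tx$low, tx$high),
      qol_altern = mk_qol(qa), qol_surg = mk_qol(qs),
      age = age_estimate(ag$mean, ag$low, ag$high),
      sources = paste(unique(rows$source), collapse = "; "))
    records[[k]] <- rec
  }
  if (anyDuplicated(names(records)))
    stop("duplicate disease-surgery-alternative key in registry", call. = FALSE)
  reg <- structure(unname(records), class = "comparison_registry")
  viol <- do.call(rbind, lapply(reg, validate_record))
  if (nrow(viol)) {
    stop("registry validation failed:\n",
         paste(sprintf("  %s / %s: %s", viol$record, viol$field, viol$rule),
               collapse = "\n"), call. = FALSE)
  }
  reg
}

#' Write a registry back to the long-format CSV schema
#'
#' Inverse of [load_registry()]: re-loading the written file yields
#' field-identical records.
#'
#' @param registry A `comparison_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  rows <- list()
  add <- function(rec, parameter, unit, mean, spread_sd = NA_real_,
                  low = NA_real_, high = NA_real_, distribution, source = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      disease = rec$disease, surgery = rec$surgery, alternative = rec$alternative,
      parameter = parameter, unit = unit, mean = mean, spread_sd = spread_sd,
      low = low, high = high, distribution = distribution, source = source)
  }
  surv_unit <- function(est) sprintf("probability %g-y survival", est$horizon_years)
  for (rec in registry) {
    src <- rec$sources
    if (!is.null(rec$surv_altern)) {
      e <- rec$surv_altern
      add(rec, "surv_altern", surv_unit(e), e$probability, e$sd, e$low, e$high, e$family, src)
    }
    e <- rec$surv_surg
    add(rec, "surv_surg", surv_unit(e), e$probability, e$sd, e$low, e$high, e$family, src)
    if (!is.null(rec$tx_eff)) {
      t <- rec$tx_eff
      add(rec, "tx_eff", "hazard ratio", t$hazard_ratio, NA_real_, t$low, t$high,
          "lognormal", src)
    }
    add(rec, "qol_altern", "utility", rec$qol_altern$mode, NA_real_,
        rec$qol_altern$low, rec$qol_altern$high, "triangular", src)
    add(rec, "qol_surg", "utility", rec$qol_surg$mode, NA_real_,
        rec$qol_surg$low, rec$qol_surg$high, "triangular", src)
    add(rec, "age", "years", rec$age$mean_years, NA_real_,
        rec$age$low, rec$age$high, "normal", src)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' The packaged parameter registry
#'
#' Loads the registry of all 23 disease-surgery-alternative combinations
#' (13 disease-surgery pairs) shipped with the package, spanning oncologic,
#' cardiovascular and elective surgical care in the Dutch setting.
#'
#' @return A `comparison_registry` of 23 records.
#' @examples
#' reg <- surgdelay_registry()
#' length(reg)
#' @export
surgdelay_registry <- function() {
  load_registry(system.file("extdata", "table2_registry.csv", package = "surgdelay",
                            mustWork = TRUE))
}

#' Summarize a registry as a data frame
#'
#' @param x A `comparison_registry`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return One row per record with the point estimates of each parameter.
#' @export
as.data.frame.comparison_registry <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    disease = r$disease, surgery = r$surgery, alternative = r$alternative,
    surv_altern = if (is.null(r$surv_altern)) NA_real_ else r$surv_altern$probability,
    surv_altern_horizon = if (is.null(r$surv_altern)) NA_real_ else r$surv_altern$horizon_years,
    surv_surg = r$surv_surg$probability,
    surv_surg_horizon = r$surv_surg$horizon_years,
    hazard_ratio = if (is.null(r$tx_eff)) NA_real_ else r$tx_eff$hazard_ratio,
    qol_altern = r$qol_altern$mode, qol_surg = r$qol_surg$mode,
    age = r$age$mean_years)))
}
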