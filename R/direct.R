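## Design-based direct estimation: cohort-flow accounting for the survey
## module, survey-weighted district prevalences, with-replacement PSU-level
## Taylor-linearised variances, and logit-scale sampling variances /
## confidence intervals used by the area-level model.

#' Cohort-flow accounting for a subsampled survey module
#'
#' Tracks respondents from the full interview sample through module
#' selection and the exclusions (never-married respondents; interviews
#' without the privacy the module requires) to the analytic sample, with
#' the derived percentages rounded to one decimal as conventionally
#' reported.
#'
#' @param n_interviewed women interviewed in the full survey.
#' @param n_dv_module women selected for the violence module.
#' @param n_excluded_never_married exclusions: never married.
#' @param n_excluded_privacy exclusions: privacy not ensured.
#' @return list of class `cohort_flow` with the input counts, `n_analytic`,
#'   and percentages `pct_dv_of_interviewed`, `pct_never_married`,
#'   `pct_privacy` (each rounded to 1 decimal, in percent).
#' @examples
#' cohort_flow(699686, 83397, 14377, 3007)$n_analytic  # 66013
#' @export
cohort_flow <- function(n_interviewed, n_dv_module,
                        n_excluded_never_married, n_excluded_privacy) {
  counts <- c(n_interviewed, n_dv_module, n_excluded_never_married,
              n_excluded_privacy)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("all counts must be non-negative integers")
  if (n_excluded_never_married + n_excluded_privacy > n_dv_module)
    stop_config("exclusions exceed the module sample size")
  if (n_dv_module > n_interviewed)
    stop_config("module sample exceeds the interviewed sample")
  structure(list(
    n_interviewed = n_interviewed,
    n_dv_module = n_dv_module,
    n_excluded_never_married = n_excluded_never_married,
    n_excluded_privacy = n_excluded_privacy,
    n_analytic = n_dv_module - n_excluded_never_married - n_excluded_privacy,
    pct_dv_of_interviewed = round(100 * n_dv_module / n_interviewed, 1),
    pct_never_married = round(100 * n_excluded_never_married / n_dv_module, 1),
    pct_privacy = round(100 * n_excluded_privacy / n_dv_module, 1)),
    class = "cohort_flow")
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat(sprintf("cohort_flow: %d interviewed -> %d in module (%.1f%%)\n",
              x$n_interviewed, x$n_dv_module, x$pct_dv_of_interviewed))
  cat(sprintf("  excluded: %d never married (%.1f%%), %d privacy (%.1f%%)\n",
              x$n_excluded_never_married, x$pct_never_married,
              x$n_excluded_privacy, x$pct_privacy))
  cat(sprintf("  analytic sample: %d\n", x$n_analytic))
  invisible(x)
}

#' Survey-weighted proportion
#'
#' @param y binary outcome vector.
#' @param w positive design weights.
#' @return sum(w * y) / sum(w).
#' @export
weighted_proportion <- function(y, w = rep(1, length(y))) {
  if (length(y) == 0) stop_config("no records")
  if (any(w <= 0)) stop_config("weights must be positive")
  sum(w * y) / sum(w)
}

#' Design-based variance of a weighted proportion (PSU linearisation)
#'
#' With-replacement first-stage Taylor linearisation: with m PSUs and PSU
#' score totals z_j = sum over PSU j of w_i (y_i - p_hat),
#' var = m/(m-1) * sum_j (z_j - mean(z))^2 / (sum_i w_i)^2. Strata and
#' finite-population corrections are ignored (the DHS-style default).
#'
#' @param y binary outcome vector.
#' @param w positive design weights.
#' @param psu PSU (cluster) identifier per record.
#' @return variance of the weighted proportion; `NA` with a warning
#'   attribute if fewer than 2 PSUs are present.
#' @export
design_variance <- function(y, w, psu) {
  p_hat <- weighted_proportion(y, w)
  z <- tapply(w * (y - p_hat), psu, sum)
  m <- length(z)
  if (m < 2) return(NA_real_)
  m / (m - 1) * sum((z - mean(z))^2) / sum(w)^2
}

#' Logit-scale sampling variance (delta method)
#'
#' Bridges the design-scale variance of a proportion to the logit scale on
#' which the area-level model operates: psi = var_p / (p(1-p))^2.
#'
#' @param p_hat proportion strictly inside (0, 1).
#' @param var_p design-based variance of `p_hat`.
#' @return psi, or `NA` when `p_hat` is 0 or 1 (undefined on the logit
#'   scale; such districts are treated as unsampled by the model stage).
#' @export
logit_variance <- function(p_hat, var_p) {
  ifelse(p_hat > 0 & p_hat < 1, var_p / (p_hat * (1 - p_hat))^2, NA_real_)
}

#' Logit-Wald confidence interval for a proportion
#'
#' expit(logit(p_hat) +/- z * sqrt(psi)); always inside (0, 1).
#'
#' @param p_hat proportion in (0, 1).
#' @param psi logit-scale sampling variance.
#' @param level confidence level.
#' @return named vector `c(ci_low, ci_high)` (vectorised: two columns).
#' @export
direct_interval <- function(p_hat, psi, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(psi)
  cbind(ci_low = expit(logit(p_hat) - half),
        ci_high = expit(logit(p_hat) + half))
}

#' Direct survey-based district estimates
#'
#' Computes, for each district and outcome, the weighted prevalence, its
#' PSU-linearised design variance, SE, CV, logit-scale sampling variance
#' psi, and a logit-Wald confidence interval. Districts with a single PSU
#' (variance undefined) or a degenerate prevalence of exactly 0 or 1
#' (logit undefined) are flagged `usable = FALSE`; the model stage treats
#' them as unsampled and they receive synthetic predictions.
#'
#' @param survey data.frame with `district_id`, `psu_id`, `weight` and the
#'   outcome columns.
#' @param outcomes outcome column names (default: every column starting
#'   with `y`).
#' @param level confidence level for the intervals.
#' @return data.frame of class `direct_estimates`, one row per district x
#'   outcome, with columns `district_id`, `outcome`, `n_respondents`,
#'   `n_psus`, `p_hat`, `var_p`, `se`, `cv`, `psi`, `ci_low`, `ci_high`,
#'   `usable`.
#' @export
direct_estimates <- function(survey, outcomes = NULL, level = 0.95) {
  need <- c("district_id", "psu_id", "weight")
  if (!all(need %in% names(survey)))
    stop_config("survey must have columns %s", paste(need, collapse = ", "))
  if (is.null(outcomes))
    outcomes <- grep("^y", names(survey), value = TRUE)
  if (length(outcomes) == 0) stop_config("no outcome columns found")
  rows <- list()
  for (oc in outcomes) {
    by_d <- split(survey, survey$district_id)
    for (id in names(by_d)) {
      d <- by_d[[id]]
      p <- weighted_proportion(d[[oc]], d$weight)
      v <- design_variance(d[[oc]], d$weight, d$psu_id)
      psi <- if (is.na(v)) NA_real_ else logit_variance(p, v)
      usable <- !is.na(psi)
      ci <- if (usable) direct_interval(p, psi, level) else
        cbind(ci_low = NA_real_, ci_high = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        district_id = id, outcome = oc,
        n_respondents = nrow(d),
        n_psus = length(unique(d$psu_id)),
        p_hat = p, var_p = v, se = sqrt(v),
        cv = if (p > 0) sqrt(v) / p else NA_real_,
        psi = psi, ci_low = ci[1], ci_high = ci[2],
        usable = usable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$outcome, out$district_id), ]
  rownames(out) <- NULL
  class(out) <- c("direct_estimates", "data.frame")
  out
}
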