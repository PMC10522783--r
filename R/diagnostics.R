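## Validity diagnostics: residual behaviour of the fitted area-level model
## (normality, homoskedasticity), the bias regression of direct on
## model-based estimates against the 45-degree line, precision (CV and
## CI-width) comparisons, and per-state variation of the model estimates.

#' Residual diagnostics for the area-level model
#'
#' Standardised marginal residuals
#' `(logit(p_hat) - x'beta) / sqrt(sigma2_u + psi)` against the predicted
#' values, with a Shapiro-Wilk normality p-value and a Breusch-Pagan
#' (studentised) homoskedasticity p-value of the residuals against the
#' predictions. Judgement is left to the caller.
#'
#' @param fit an `fh_fit` (at least 10 in-sample districts).
#' @return list of class `residual_diagnostic`: data.frame `residuals`
#'   (`district_id`, `predicted`, `residual_std`), `shapiro_p`, `bp_p`.
#' @export
residual_diagnostic <- function(fit) {
  stopifnot(inherits(fit, "fh_fit"))
  if (length(fit$y) < 10)
    stop_config("need >= 10 in-sample districts for residual diagnostics")
  predicted <- as.numeric(fit$X %*% fit$beta_hat)
  res <- (fit$y - predicted) / sqrt(fit$sigma2_u_hat + fit$psi)
  shapiro_p <- if (stats::var(res) > 0) stats::shapiro.test(res)$p.value else
    NA_real_
  bp_p <- if (stats::var(predicted) > 0 && stats::var(res) > 0) {
    lmtest::bptest(stats::lm(res ~ predicted))$p.value
  } else NA_real_
  structure(list(residuals = data.frame(district_id = fit$district_id,
                                        predicted = predicted,
                                        residual_std = res,
                                        stringsAsFactors = FALSE),
                 shapiro_p = unname(shapiro_p), bp_p = unname(bp_p)),
            class = "residual_diagnostic")
}

#' Bias regression of direct on model-based estimates
#'
#' OLS of the direct estimates (y) on the model's predictions (x) on the
#' proportion scale, over in-sample districts with usable direct
#' estimates, with t-tests of slope = 1 and intercept = 0. Agreement with
#' the 45-degree line (both tests non-significant) indicates the
#' model-based estimates are consistent with the design-based ones.
#'
#' With `predictor = "synthetic"` (default) the regressor is the model's
#' covariate prediction `expit(x'beta)`: under a correctly specified model
#' the direct estimate is this prediction plus zero-mean noise, so the
#' slope-1/intercept-0 tests are calibrated. With `predictor = "eblup"`
#' the regressor is the shrinkage estimate itself; because the EBLUP is
#' built from the same direct estimate, that regression has expected slope
#' `(V + sigma2_u) / (V + sigma2_u - gamma psi) > 1` even under a correct
#' model (V = between-district variance of the covariate predictions), so
#' it describes agreement but is not a calibrated test.
#'
#' @param direct a `direct_estimates` table.
#' @param sae an `sae_estimates` table (same outcome).
#' @param predictor `"synthetic"` (calibrated, default) or `"eblup"`.
#' @return list of class `bias_diagnostic` with `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `t_slope_vs_1`, `p_slope_vs_1`,
#'   `t_intercept_vs_0`, `p_intercept_vs_0`, `n_districts_used`.
#' @export
bias_regression <- function(direct, sae,
                            predictor = c("synthetic", "eblup")) {
  predictor <- match.arg(predictor)
  xcol <- if (predictor == "synthetic" && "theta_syn" %in% names(sae))
    "theta_syn" else "theta_hat"
  sae <- sae[, c("district_id", "in_sample", xcol)]
  names(sae)[3] <- "theta_hat"
  m <- merge(direct[direct$usable, c("district_id", "p_hat")],
             sae[sae$in_sample, c("district_id", "theta_hat")],
             by = "district_id")
  n <- nrow(m)
  if (n < 3) stop_config("need >= 3 matched districts")
  if (stats::var(m$theta_hat) == 0)
    stop_config("model-based estimates have zero variance")
  fit <- stats::lm(p_hat ~ theta_hat, data = m)
  # a perfect fit (zero residual SE) is legitimate here; handled below
  cf <- suppressWarnings(summary(fit))$coefficients
  tstat <- function(est, null, se) {
    if (abs(est - null) < 1e-12) 0 else if (se == 0) Inf else (est - null) / se
  }
  t_s <- tstat(cf[2, 1], 1, cf[2, 2])
  t_i <- tstat(cf[1, 1], 0, cf[1, 2])
  pval <- function(t) {
    if (t == 0) 1 else 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
                 se_slope = unname(cf[2, 2]), se_intercept = unname(cf[1, 2]),
                 t_slope_vs_1 = t_s, p_slope_vs_1 = pval(t_s),
                 t_intercept_vs_0 = t_i, p_intercept_vs_0 = pval(t_i),
                 n_districts_used = n),
            class = "bias_diagnostic")
}

#' Precision comparison of direct and model-based estimates
#'
#' Per matched district, the CVs and 95% CI widths of both methods, with
#' the share of districts whose model-based CV improves on the direct CV
#' and the median CV ratio (model / direct).
#'
#' @param direct a `direct_estimates` table (with CIs).
#' @param sae an `sae_estimates` table carrying `cv`, `ci_low`, `ci_high`
#'   from [fh_mse()].
#' @return list of class `precision_comparison`: data.frame `by_district`
#'   (sorted by district id), `share_cv_improved`, `median_cv_ratio`.
#' @export
precision_comparison <- function(direct, sae) {
  m <- merge(direct[direct$usable,
                    c("district_id", "cv", "ci_low", "ci_high")],
             sae[sae$in_sample, c("district_id", "cv", "ci_low", "ci_high")],
             by = "district_id", suffixes = c("_direct", "_model"))
  m <- m[order(m$district_id), ]
  out <- data.frame(district_id = m$district_id,
                    cv_direct = m$cv_direct, cv_model = m$cv_model,
                    ci_width_direct = m$ci_high_direct - m$ci_low_direct,
                    ci_width_model = m$ci_high_model - m$ci_low_model,
                    stringsAsFactors = FALSE)
  structure(list(by_district = out,
                 share_cv_improved = mean(out$cv_model < out$cv_direct),
                 median_cv_ratio = stats::median(out$cv_model / out$cv_direct)),
            class = "precision_comparison")
}

#' Per-state variation of model-based district estimates
#'
#' For each state, the coefficient of variation of its districts'
#' model-based prevalences: population SD (divisor n) over the mean. A
#' descriptive measure of intrastate heterogeneity.
#'
#' @param sae an `sae_estimates` table.
#' @param aux auxiliary table mapping `district_id` to `state_id`.
#' @return data.frame with `state_id`, `n_districts`, `mean_theta`,
#'   `cv_theta`, `single_district` (flag: CV is 0 by construction).
#' @export
state_variation <- function(sae, aux) {
  st <- aux$state_id[match(sae$district_id, aux$district_id)]
  if (anyNA(st)) stop_config("districts missing from aux: %s",
                             paste(sae$district_id[is.na(st)], collapse = ", "))
  sp <- split(sae$theta_hat, st)
  out <- data.frame(
    state_id = names(sp),
    n_districts = lengths(sp),
    mean_theta = vapply(sp, mean, 0),
    cv_theta = vapply(sp, function(x) {
      if (length(x) == 1) return(0)
      sqrt(mean((x - mean(x))^2)) / mean(x)
    }, 0),
    stringsAsFactors = FALSE)
  out$single_district <- out$n_districts == 1
  rownames(out) <- NULL
  out
}
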