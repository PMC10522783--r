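## Orchestration: one reproducible run of
## synth -> geometry -> direct -> area model -> diagnostics -> LISA from a
## single configuration, writing every stage artefact plus a manifest; and
## the Monte-Carlo recovery experiment that validates the whole chain
## against known truth.

#' Read a generator configuration from JSON
#'
#' The JSON keys mirror the [synth_config()] arguments; absent keys take
#' the defaults.
#'
#' @param path JSON file path.
#' @return a `synth_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  bad <- setdiff(names(obj), known)
  if (length(bad) > 0)
    stop_config("unknown config fields: %s", paste(bad, collapse = ", "))
  if (!is.null(obj$outcomes)) obj$outcomes <- unlist(obj$outcomes)
  do.call(synth_config, obj)
}

## per-outcome truth: the configured beta with the outcome's intercept shift
outcome_truths <- function(aux, config) {
  out <- list()
  for (k in seq_along(config$outcomes)) {
    beta <- config$beta_true
    beta[1] <- beta[1] + config$outcomes[k]
    out[[names(config$outcomes)[k]]] <- generate_truth(
      aux, beta, config$sigma_u_true,
      seed = derive_seed(config$seed, 30 + k),
      covariates = config$truth_covariates)
  }
  out
}

#' Run the full pipeline
#'
#' Executes geography, auxiliary, truth and survey generation, direct
#' estimation, the area-level model with bootstrap MSEs, diagnostics, and
#' LISA classification, one outcome at a time, writing each stage's
#' artefact under `out_dir` and a `manifest.json` last. Re-running with an
#' identical configuration reproduces identical outputs (per-stage seeds
#' are derived from the master seed by fixed offsets). User-supplied
#' `survey`, `aux` and `geography` tables may be passed to skip the
#' synthetic stages.
#'
#' @param config a `synth_config` (or path to a JSON config).
#' @param out_dir output directory (created if needed).
#' @param bootstrap_B bootstrap replicates for the MSE stage.
#' @param n_perm,alpha LISA permutation count and significance level.
#' @param survey,aux,geography optional user-supplied inputs overriding
#'   the synthetic stages (all three of `aux` and `geography` are required
#'   with `survey`).
#' @param fit_covariates covariates for the model stage (default: all
#'   covariate columns of `aux`, including `bpf`).
#' @param include_state include state fixed effects in the model.
#' @return the run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_all <- function(config, out_dir, bootstrap_B = 200, n_perm = 999,
                    alpha = 0.05, survey = NULL, aux = NULL,
                    geography = NULL, fit_covariates = NULL,
                    include_state = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("stage %s failed: %s", name, conditionMessage(e))
    })
  }
  truth_list <- NULL
  if (is.null(geography)) {
    geography <- stage("synth/geography",
                       generate_geography(config$n_states,
                                          config$districts_per_state,
                                          seed = derive_seed(config$seed, 1)))
  }
  paths$geography <- file.path(out_dir, "geography.geojson")
  write_geojson(geography, paths$geography)
  if (is.null(aux)) {
    aux <- stage("synth/auxiliary",
                 generate_auxiliary(geography, config$spatial_range,
                                    seed = derive_seed(config$seed, 2),
                                    n_covariates = config$n_covariates))
  }
  paths$aux <- file.path(out_dir, "aux.csv")
  utils::write.csv(aux, paths$aux, row.names = FALSE)
  if (is.null(survey)) {
    truth_list <- stage("synth/truth", outcome_truths(aux, config))
    survey <- stage("synth/survey",
                    sample_survey(truth_list, config,
                                  seed = derive_seed(config$seed, 4)))
    truth_df <- do.call(rbind, lapply(names(truth_list), function(nm) {
      tt <- truth_list[[nm]]
      data.frame(outcome = nm, district_id = tt$district_id,
                 theta_true = tt$theta_true, u_true = tt$u_true,
                 stringsAsFactors = FALSE)
    }))
    paths$truth <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth_df, paths$truth, row.names = FALSE)
  }
  paths$survey <- file.path(out_dir, "survey.csv")
  utils::write.csv(survey, paths$survey, row.names = FALSE)

  weights <- stage("geometry/weights", queen_weights(geography))
  paths$weights <- file.path(out_dir, "weights.json")
  write_weights(weights, paths$weights)
  bpf <- stage("geometry/bpf", compute_bpf(geography))
  paths$bpf <- file.path(out_dir, "bpf.csv")
  utils::write.csv(bpf, paths$bpf, row.names = FALSE)

  outcomes <- grep("^y", names(survey), value = TRUE)
  direct <- stage("direct", direct_estimates(survey, outcomes))
  paths$direct <- file.path(out_dir, "direct.csv")
  utils::write.csv(direct, paths$direct, row.names = FALSE)

  sae_all <- list(); fits <- list(); diag_all <- list(); lisa_all <- list()
  for (k in seq_along(outcomes)) {
    oc <- outcomes[k]
    fit <- stage(paste0("areamodel/fit/", oc),
                 fh_fit(direct, aux, outcome = oc,
                        covariates = fit_covariates,
                        include_state = include_state))
    sae <- stage(paste0("areamodel/mse/", oc),
                 fh_mse(fit, direct, aux, B = bootstrap_B,
                        seed = derive_seed(config$seed, 50 + k)))
    rd <- stage(paste0("diagnostics/residuals/", oc), residual_diagnostic(fit))
    br <- stage(paste0("diagnostics/bias/", oc), bias_regression(direct, sae))
    pc <- stage(paste0("diagnostics/precision/", oc),
                precision_comparison(direct, sae))
    sv <- stage(paste0("diagnostics/state_cv/", oc), state_variation(sae, aux))
    theta <- stats::setNames(sae$theta_hat, sae$district_id)
    li <- stage(paste0("lisa/", oc),
                local_moran(theta, weights, n_perm = n_perm, alpha = alpha,
                            seed = derive_seed(config$seed, 70 + k)))
    li$outcome <- oc
    fits[[oc]] <- fit
    sae_all[[oc]] <- sae
    lisa_all[[oc]] <- li
    rd$residuals$outcome <- oc
    sv$outcome <- oc
    diag_all[[oc]] <- list(
      residuals = rd$residuals,
      shapiro_p = rd$shapiro_p, bp_p = rd$bp_p,
      bias = unclass(br),
      precision = list(by_district = pc$by_district,
                       share_cv_improved = pc$share_cv_improved,
                       median_cv_ratio = pc$median_cv_ratio),
      state_cv = sv)
  }
  sae_df <- do.call(rbind, sae_all); rownames(sae_df) <- NULL
  paths$sae <- file.path(out_dir, "sae.csv")
  utils::write.csv(sae_df, paths$sae, row.names = FALSE)
  lisa_df <- do.call(rbind, lisa_all); rownames(lisa_df) <- NULL
  paths$lisa <- file.path(out_dir, "lisa.csv")
  utils::write.csv(lisa_df, paths$lisa, row.names = FALSE)
  paths$fit <- file.path(out_dir, "fit.json")
  jsonlite::write_json(lapply(fits, function(f) {
    list(outcome = f$outcome, beta_hat = as.list(f$beta_hat),
         se_beta = as.list(f$se_beta), sigma2_u_hat = f$sigma2_u_hat,
         loglik = f$loglik, n_iterations = f$n_iterations,
         converged = f$converged, boundary = f$boundary)
  }), paths$fit, auto_unbox = TRUE, digits = NA)
  paths$diagnostics <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(lapply(diag_all, function(d) {
    d$residuals <- NULL; d$precision$by_district <- NULL; d
  }), paths$diagnostics, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths$residuals <- file.path(out_dir, "residuals.csv")
  utils::write.csv(do.call(rbind, lapply(diag_all, `[[`, "residuals")),
                   paths$residuals, row.names = FALSE)
  paths$cv_comparison <- file.path(out_dir, "cv_comparison.csv")
  utils::write.csv(do.call(rbind, lapply(names(diag_all), function(oc) {
    b <- diag_all[[oc]]$precision$by_district; b$outcome <- oc; b
  })), paths$cv_comparison, row.names = FALSE)
  paths$state_cv <- file.path(out_dir, "state_cv.csv")
  utils::write.csv(do.call(rbind, lapply(diag_all, `[[`, "state_cv")),
                   paths$state_cv, row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    config_hash = hash_object(unclass(config)),
    seeds = list(geography = derive_seed(config$seed, 1),
                 auxiliary = derive_seed(config$seed, 2),
                 survey = derive_seed(config$seed, 4),
                 mse = sapply(seq_along(outcomes),
                              function(k) derive_seed(config$seed, 50 + k)),
                 lisa = sapply(seq_along(outcomes),
                               function(k) derive_seed(config$seed, 70 + k))),
    stage_order = c("synth", "geometry", "direct", "areamodel",
                    "diagnostics", "lisa"),
    files = lapply(paths, function(p) {
      list(path = p,
           n_rows = tryCatch(
             if (grepl("\\.csv$", p)) nrow(utils::read.csv(p)) else NA,
             error = function(e) NA),
           md5 = unname(tools::md5sum(p)))
    }),
    version = as.character(utils::packageVersion("saeipv")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  structure(manifest, class = "run_manifest")
}

#' Monte-Carlo recovery experiment
#'
#' Holds the map and auxiliary covariates fixed, redraws truth and survey
#' `n_replicates` times, and runs direct estimation, the area-level fit
#' (on the generative covariates, matching the model under which truth was
#' drawn) and the bootstrap MSE stage on each replicate. Records
#' per-replicate coefficient estimates, the area-variance estimate,
#' empirical coverage of the model-based intervals for the true
#' prevalences, the share of districts whose model CV beats the direct
#' CV, and the bias-regression slope test p-value.
#'
#' @param config a `synth_config`; its `beta_true`, `sigma_u_true` and
#'   design sizes define the experiment.
#' @param n_replicates number of replicates (>= 10).
#' @param bootstrap_B bootstrap replicates per fit for MSE/coverage.
#' @param out_csv optional path for the per-replicate table.
#' @return list of class `recovery_experiment`: data.frame `replicates`,
#'   data.frame `beta_summary` (truth, mean estimate, bias, Monte-Carlo
#'   SE, RMSE per coefficient), and `summary` (sigma2_u mean/bias/MC-SE,
#'   mean coverage, mean CV-improvement share, slope-test non-rejection
#'   rate).
#' @export
recovery_experiment <- function(config, n_replicates = 50, bootstrap_B = 100,
                                out_csv = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (n_replicates < 10) stop_config("n_replicates must be >= 10")
  geography <- generate_geography(config$n_states, config$districts_per_state,
                                  seed = derive_seed(config$seed, 1))
  aux <- generate_auxiliary(geography, config$spatial_range,
                            seed = derive_seed(config$seed, 2),
                            n_covariates = config$n_covariates)
  p <- length(config$beta_true)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    truth <- generate_truth(aux, config$beta_true, config$sigma_u_true,
                            seed = derive_seed(config$seed, 100 + 7 * r),
                            covariates = config$truth_covariates)
    survey <- sample_survey(truth, config,
                            seed = derive_seed(config$seed, 101 + 7 * r))
    direct <- direct_estimates(survey)
    fit <- fh_fit(direct, aux, covariates = config$truth_covariates,
                  include_state = FALSE)
    sae <- fh_mse(fit, direct, aux, B = bootstrap_B,
                  seed = derive_seed(config$seed, 102 + 7 * r))
    th <- truth$theta_true[match(sae$district_id, truth$district_id)]
    covered <- mean(sae$ci_low <= th & th <= sae$ci_high)
    pc <- precision_comparison(direct, sae)
    br <- bias_regression(direct, sae)
    row <- c(replicate = r, stats::setNames(fit$beta_hat, paste0("beta_", seq_len(p) - 1)),
             sigma2_u_hat = fit$sigma2_u_hat, coverage = covered,
             share_cv_improved = pc$share_cv_improved,
             p_slope_vs_1 = br$p_slope_vs_1)
    reps[[r]] <- as.data.frame(as.list(row))
  }
  reps <- do.call(rbind, reps)
  bcols <- paste0("beta_", seq_len(p) - 1)
  beta_summary <- data.frame(
    coefficient = bcols,
    truth = config$beta_true,
    mean_estimate = colMeans(reps[bcols]),
    bias = colMeans(reps[bcols]) - config$beta_true,
    mc_se = apply(reps[bcols], 2, stats::sd) / sqrt(n_replicates),
    rmse = sqrt(colMeans((t(t(as.matrix(reps[bcols])) - config$beta_true))^2)),
    stringsAsFactors = FALSE)
  rownames(beta_summary) <- NULL
  summary <- list(
    n_replicates = n_replicates,
    sigma2_u_true = config$sigma_u_true^2,
    sigma2_u_mean = mean(reps$sigma2_u_hat),
    sigma2_u_bias = mean(reps$sigma2_u_hat) - config$sigma_u_true^2,
    sigma2_u_mc_se = stats::sd(reps$sigma2_u_hat) / sqrt(n_replicates),
    mean_coverage = mean(reps$coverage),
    mean_share_cv_improved = mean(reps$share_cv_improved),
    slope_nonreject_rate = mean(reps$p_slope_vs_1 > 0.05))
  if (!is.null(out_csv)) utils::write.csv(reps, out_csv, row.names = FALSE)
  structure(list(replicates = reps, beta_summary = beta_summary,
                 summary = summary),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("recovery_experiment: %d replicates\n", s$n_replicates))
  print(transform(x$beta_summary,
                  mean_estimate = round(mean_estimate, 4),
                  bias = round(bias, 4), mc_se = round(mc_se, 4),
                  rmse = round(rmse, 4)))
  cat(sprintf("  sigma2_u: truth %.4f, mean estimate %.4f (MC-SE %.4f)\n",
              s$sigma2_u_true, s$sigma2_u_mean, s$sigma2_u_mc_se))
  cat(sprintf("  95%% CI coverage %.3f | share CV improved %.3f | slope test non-rejection %.2f\n",
              s$mean_coverage, s$mean_share_cv_improved,
              s$slope_nonreject_rate))
  invisible(x)
}
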