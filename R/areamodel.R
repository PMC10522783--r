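## Logit-scale area-level (Fay-Herriot) model:
##   logit(p_hat_d) = x_d' beta + u_d + e_d,  u_d ~ N(0, sigma2_u),
##   e_d ~ N(0, psi_d) with psi_d known from the direct-estimation stage.
## beta by GLS given sigma2_u; sigma2_u by profile maximum likelihood
## (Brent search on [0, upper]). EBLUP prediction shrinks the direct
## estimate towards the synthetic (covariate) prediction with factor
## gamma_d = sigma2_u / (sigma2_u + psi_d).

## GLS for beta at a given sigma2; returns beta, its covariance and the
## profile (restricted) log-likelihood pieces.
fh_gls <- function(sigma2, y, X, psi, reml = FALSE) {
  V <- sigma2 + psi
  Xw <- X / V
  XtVX <- crossprod(X, Xw)
  beta <- solve(XtVX, crossprod(Xw, y))
  r <- y - as.numeric(X %*% beta)
  ll <- -0.5 * sum(log(V)) - 0.5 * sum(r^2 / V)
  if (reml) ll <- ll - 0.5 * determinant(XtVX, logarithm = TRUE)$modulus
  list(beta = as.numeric(beta), cov_beta = solve(XtVX), loglik = as.numeric(ll),
       resid = r)
}

## Design matrix for the area model: intercept + covariates (+ state
## dummies, reference = first state id in sort order).
fh_design <- function(aux, covariates, include_state) {
  X <- cbind(`(Intercept)` = 1, as.matrix(aux[covariates]))
  if (include_state) {
    st <- factor(aux$state_id, levels = sort(unique(aux$state_id)))
    if (nlevels(st) > 1) {
      S <- stats::model.matrix(~st)[, -1, drop = FALSE]
      colnames(S) <- paste0("state_", levels(st)[-1])
      X <- cbind(X, S)
    }
  }
  X
}

#' Fit the logit-scale area-level model
#'
#' Links logit-transformed direct district estimates to auxiliary
#' covariates with a Normal district random effect, treating each
#' district's logit-scale sampling variance `psi` as known. `sigma2_u` is
#' estimated by profile maximum likelihood (Brent search over
#' \[0, 10 x var(logit direct)\]); `beta` is the GLS estimate at the
#' optimum. A likelihood maximised at the boundary `sigma2_u = 0` is
#' reported as a boundary fit (flag `boundary`), not jittered.
#'
#' @param direct a `direct_estimates` table (or compatible data.frame).
#' @param aux auxiliary table with `district_id`, `state_id` and covariate
#'   columns.
#' @param outcome outcome name to fit (default: the only outcome present).
#' @param covariates covariate columns (default: all covariate columns of
#'   `aux`, including `bpf`).
#' @param include_state add state-of-residence fixed effects (one-hot,
#'   reference = first state id in sort order).
#' @param method `"ML"` (default) or `"REML"`.
#' @return object of class `fh_fit`: `beta_hat`, `se_beta`, `sigma2_u_hat`,
#'   `loglik`, `n_iterations` (likelihood evaluations), `converged`,
#'   `boundary`, plus the in-sample data (`y`, `X`, `psi`, `district_id`)
#'   needed by [fh_predict()] and [fh_mse()].
#' @export
fh_fit <- function(direct, aux, outcome = NULL, covariates = NULL,
                   include_state = TRUE, method = c("ML", "REML")) {
  method <- match.arg(method)
  if (is.null(outcome)) {
    outcome <- unique(direct$outcome)
    if (length(outcome) != 1)
      stop_config("multiple outcomes present; pick one via `outcome`")
  }
  d <- direct[direct$outcome == outcome & direct$usable, , drop = FALSE]
  if (!all(d$district_id %in% aux$district_id))
    stop_config("districts missing from aux: %s",
                paste(setdiff(d$district_id, aux$district_id), collapse = ", "))
  if (is.null(covariates)) covariates <- aux_covariate_names(aux)
  a <- aux[match(d$district_id, aux$district_id), , drop = FALSE]
  X <- fh_design(a, covariates, include_state)
  p <- ncol(X)
  if (nrow(X) < p + 2)
    stop_config("only %d usable districts for %d parameters", nrow(X), p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_config("design matrix rank-deficient; collinear columns: %s",
                paste(bad, collapse = ", "))
  }
  y <- logit(d$p_hat)
  psi <- d$psi
  upper <- max(10 * stats::var(y), 1e-6)  # guard: constant y
  reml <- method == "REML"
  n_eval <- 0L
  obj <- function(s2) {
    n_eval <<- n_eval + 1L
    -fh_gls(s2, y, X, psi, reml)$loglik
  }
  opt <- stats::optimize(obj, c(0, upper), tol = 1e-10)
  # compare the interior optimum with the boundary
  ll0 <- fh_gls(0, y, X, psi, reml)$loglik
  sigma2 <- if (ll0 >= -opt$objective) 0 else opt$minimum
  boundary <- sigma2 == 0 ||
    (upper - sigma2) < 1e-6 * upper  # hit the search ceiling
  g <- fh_gls(sigma2, y, X, psi, reml)
  # numerical gradient check at an interior optimum
  converged <- TRUE
  if (sigma2 > 0 && sigma2 < upper) {
    h <- max(1e-8, 1e-6 * sigma2)
    grad <- (fh_gls(sigma2 + h, y, X, psi, reml)$loglik -
             fh_gls(max(0, sigma2 - h), y, X, psi, reml)$loglik) / (2 * h)
    # profile loglik gradient near zero at an interior optimum
    converged <- abs(grad) * h < 1e-6 * max(1, abs(g$loglik))
  }
  structure(list(outcome = outcome,
                 beta_hat = stats::setNames(g$beta, colnames(X)),
                 se_beta = stats::setNames(sqrt(diag(g$cov_beta)), colnames(X)),
                 sigma2_u_hat = sigma2,
                 loglik = g$loglik,
                 n_iterations = n_eval,
                 converged = converged,
                 boundary = boundary,
                 method = method,
                 covariates = covariates,
                 include_state = include_state,
                 district_id = d$district_id,
                 y = y, X = X, psi = psi),
            class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  cat(sprintf("Area-level model fit (%s), outcome %s: %d in-sample districts\n",
              x$method, x$outcome, length(x$y)))
  cat(sprintf("  sigma2_u = %.5f%s, loglik = %.3f, %d likelihood evaluations\n",
              x$sigma2_u_hat, if (x$boundary) " (boundary)" else "",
              x$loglik, x$n_iterations))
  print(round(cbind(estimate = x$beta_hat, se = x$se_beta), 4))
  invisible(x)
}

#' Model-based (EBLUP) district estimates
#'
#' For in-sample districts, the EBLUP on the logit scale,
#' `eta = x'beta + gamma (logit(p_hat) - x'beta)` with
#' `gamma = sigma2_u / (sigma2_u + psi)`; for districts without a usable
#' direct estimate, the synthetic prediction `x'beta` (gamma = 0). Every
#' district of `aux` receives exactly one row.
#'
#' @param fit an `fh_fit`.
#' @param direct the `direct_estimates` table used in the fit.
#' @param aux auxiliary table covering all districts.
#' @return data.frame of class `sae_estimates` with `district_id`,
#'   `outcome`, `eta_hat`, `theta_hat`, `theta_syn` (the synthetic
#'   prediction `expit(x'beta)`), `gamma`, `in_sample` (MSE columns are
#'   added by [fh_mse()]).
#' @export
fh_predict <- function(fit, direct, aux) {
  stopifnot(inherits(fit, "fh_fit"))
  X_all <- fh_design(aux, fit$covariates, fit$include_state)
  X_all <- X_all[, names(fit$beta_hat), drop = FALSE]
  eta_syn <- as.numeric(X_all %*% fit$beta_hat)
  idx <- match(aux$district_id, fit$district_id)
  in_sample <- !is.na(idx)
  gamma <- rep(0, nrow(aux))
  eta <- eta_syn
  gamma[in_sample] <- fit$sigma2_u_hat /
    (fit$sigma2_u_hat + fit$psi[idx[in_sample]])
  eta[in_sample] <- eta_syn[in_sample] +
    gamma[in_sample] * (fit$y[idx[in_sample]] - eta_syn[in_sample])
  out <- data.frame(district_id = aux$district_id, outcome = fit$outcome,
                    eta_hat = eta, theta_hat = expit(eta),
                    theta_syn = expit(eta_syn), gamma = gamma,
                    in_sample = in_sample, stringsAsFactors = FALSE)
  class(out) <- c("sae_estimates", "data.frame")
  out
}

## Gauss-Hermite nodes/weights by Golub-Welsch (for the bias-corrected
## back-transform E[expit(N(eta, mse))]).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}

#' Parametric-bootstrap MSE, intervals and CVs for model-based estimates
#'
#' For b = 1..B, draws `u* ~ N(0, sigma2_u_hat)` for every district and
#' `e* ~ N(0, psi_d)` for in-sample districts, forms bootstrap direct
#' logits `x'beta + u* + e*`, refits the model, and predicts. The MSE of a
#' district's logit-scale estimate is the mean squared deviation of the
#' bootstrap prediction from the bootstrap truth `x'beta + u*` (for
#' out-of-sample districts this reduces to the synthetic-part uncertainty
#' plus `sigma2_u`). Intervals are `expit(eta +/- z sqrt(mse))`; the CV is
#' the delta-method root-MSE on the proportion scale divided by the point
#' estimate.
#'
#' @param fit an `fh_fit`.
#' @param direct,aux as in [fh_predict()].
#' @param B number of bootstrap replicates (>= 50).
#' @param seed integer seed (results are deterministic given it).
#' @param level confidence level.
#' @param backtransform `"naive"` (theta = expit(eta), default) or
#'   `"bias_corrected"` (41-node Gauss-Hermite integration of expit over
#'   N(eta, mse)).
#' @return the [fh_predict()] table augmented with `mse_eta`, `ci_low`,
#'   `ci_high`, `cv`.
#' @export
fh_mse <- function(fit, direct, aux, B = 200, seed = 1L, level = 0.95,
                   backtransform = c("naive", "bias_corrected")) {
  stopifnot(inherits(fit, "fh_fit"))
  backtransform <- match.arg(backtransform)
  if (B < 50) stop_config("B must be >= 50")
  pred <- fh_predict(fit, direct, aux)
  X_all <- fh_design(aux, fit$covariates, fit$include_state)
  X_all <- X_all[, names(fit$beta_hat), drop = FALSE]
  eta_syn <- as.numeric(X_all %*% fit$beta_hat)
  idx <- match(fit$district_id, aux$district_id)  # in-sample rows of aux
  n_all <- nrow(aux)
  sq <- matrix(0, n_all, B)
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      u_star <- stats::rnorm(n_all, 0, sqrt(fit$sigma2_u_hat))
      e_star <- stats::rnorm(length(idx), 0, sqrt(fit$psi))
      y_star <- eta_syn[idx] + u_star[idx] + e_star
      fit_b <- tryCatch({
        n_eval <- 0L
        obj <- function(s2) -fh_gls(s2, y_star, fit$X, fit$psi,
                                    fit$method == "REML")$loglik
        opt <- stats::optimize(obj, c(0, 10 * stats::var(y_star)), tol = 1e-9)
        s2 <- if (-obj(0) >= -opt$objective) 0 else opt$minimum
        g <- fh_gls(s2, y_star, fit$X, fit$psi)
        list(sigma2 = s2, beta = g$beta)
      }, error = function(e) NULL)
      if (is.null(fit_b)) { failures <- failures + 1L; sq[, b] <- NA; next }
      eta_syn_b <- as.numeric(X_all %*% fit_b$beta)
      gamma_b <- rep(0, n_all)
      gamma_b[idx] <- fit_b$sigma2 / (fit_b$sigma2 + fit$psi)
      eta_b <- eta_syn_b
      eta_b[idx] <- eta_syn_b[idx] + gamma_b[idx] * (y_star - eta_syn_b[idx])
      truth_b <- eta_syn + u_star
      sq[, b] <- (eta_b - truth_b)^2
    }
  })
  if (failures > 0.1 * B)
    stop_config("bootstrap refit failed in %d of %d replicates", failures, B)
  mse <- rowMeans(sq, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  pred$mse_eta <- mse
  if (backtransform == "bias_corrected") {
    gh <- gauss_hermite(41)
    pred$theta_hat <- vapply(seq_len(n_all), function(i) {
      sum(gh$weights / sqrt(pi) *
            expit(pred$eta_hat[i] + sqrt(2 * mse[i]) * gh$nodes))
    }, 0)
  }
  pred$ci_low <- expit(pred$eta_hat - z * sqrt(mse))
  pred$ci_high <- expit(pred$eta_hat + z * sqrt(mse))
  pred$cv <- sqrt(mse) * pred$theta_hat * (1 - pred$theta_hat) / pred$theta_hat
  pred
}
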