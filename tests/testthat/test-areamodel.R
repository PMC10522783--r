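test_that("intercept-only balanced fit matches the closed-form ML solution", {
  set.seed(19)
  n <- 40
  psi <- 0.05
  y <- rnorm(n, -1, sqrt(0.08 + psi))
  de <- manual_direct(y, rep(psi, n))
  aux <- manual_aux(de$district_id)
  fit <- fh_fit(de, aux, covariates = character(0), include_state = FALSE)

  # closed form: beta0 = mean(y); sigma2 = max(0, ML variance - psi)
  expect_equal(unname(fit$beta_hat), mean(y), tolerance = 1e-6)
  sigma2_cf <- max(0, var(y) * (n - 1) / n - psi)
  expect_equal(fit$sigma2_u_hat, sigma2_cf, tolerance = 1e-6)
  expect_true(fit$converged)

  # grid-search oracle over (beta0, sigma2): joint loglik never beats the fit
  grid_ll <- function(b0, s2) {
    V <- s2 + psi
    -0.5 * sum(log(V) + (y - b0)^2 / V)
  }
  best <- -Inf
  for (b0 in seq(mean(y) - 0.2, mean(y) + 0.2, length.out = 41))
    for (s2 in seq(0, 0.3, length.out = 61))
      best <- max(best, grid_ll(b0, s2))
  expect_gte(fit$loglik + 1e-8, best)
})

test_that("a null area variance is recovered as a boundary fit", {
  n <- 60
  psi <- 0.04
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    y <- rnorm(n, 0.2, sqrt(psi))  # sigma_u = 0 truth
    de <- manual_direct(y, rep(psi, n))
    fit <- fh_fit(de, manual_aux(de$district_id),
                  covariates = character(0), include_state = FALSE)
    hits <- hits + (fit$sigma2_u_hat == 0 && fit$boundary)
  }
  expect_gt(hits, 10)
})

test_that("fit validation catches rank deficiency and small samples", {
  set.seed(2)
  de <- manual_direct(rnorm(12), rep(0.05, 12))
  aux <- manual_aux(de$district_id)
  aux$a <- runif(12)
  aux$b <- aux$a * 2  # collinear
  expect_error(fh_fit(de, aux, covariates = c("a", "b"),
                      include_state = FALSE), "collinear")
  expect_error(fh_fit(de[1:3, ], aux[1:3, ], covariates = "a",
                      include_state = FALSE), "usable districts")
})

test_that("EBLUP prediction interpolates between synthetic and direct", {
  # gamma = 0.5 midpoint: logit direct 0, synthetic 2 -> eta 1
  fit <- manual_fh_fit(beta0 = 2, sigma2_u = 0.3, district_id = "D001",
                       y = 0, psi = 0.3)
  aux <- manual_aux(c("D001", "D002"))
  pr <- fh_predict(fit, NULL, aux)
  expect_equal(pr$gamma, c(0.5, 0))
  expect_equal(pr$eta_hat, c(1, 2))
  expect_equal(pr$theta_hat[1], 0.7310586, tolerance = 1e-6)
  expect_false(pr$in_sample[2])

  # psi -> 0 (gamma -> 1): prediction reproduces the direct estimate
  fit1 <- manual_fh_fit(2, 0.3, "D001", y = 0, psi = 1e-12)
  pr1 <- fh_predict(fit1, NULL, manual_aux("D001"))
  expect_equal(pr1$theta_hat, 0.5, tolerance = 1e-9)

  # sigma2 = 0 (gamma = 0): fully synthetic for every district
  fit0 <- manual_fh_fit(2, 0, "D001", y = 0, psi = 0.3)
  pr0 <- fh_predict(fit0, NULL, manual_aux(c("D001", "D002")))
  expect_equal(pr0$theta_hat, rep(plogis(2), 2))

  # shrinkage monotonicity and betweenness on a real fit
  set.seed(8)
  psi <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  y <- rnorm(25, -0.5, 0.4)
  de <- manual_direct(y, rep(psi, 5))
  fit2 <- fh_fit(de, manual_aux(de$district_id),
                 covariates = character(0), include_state = FALSE)
  pr2 <- fh_predict(fit2, de, manual_aux(de$district_id))
  xb <- unname(fit2$beta_hat)
  expect_true(all(pr2$eta_hat >= pmin(xb, y) - 1e-12 &
                  pr2$eta_hat <= pmax(xb, y) + 1e-12))
  g_by_psi <- tapply(pr2$gamma, rep(psi, 5), unique)
  expect_true(all(diff(unlist(g_by_psi)) < 0))
})

test_that("bootstrap MSE is deterministic, vanishes without noise, and matches the Prasad-Rao leading term", {
  set.seed(23)
  n <- 100
  psi <- 0.1
  sigma2 <- 0.1
  y <- rnorm(n, -1, sqrt(sigma2 + psi))
  de <- manual_direct(y, rep(psi, n))
  aux <- manual_aux(de$district_id)
  fit <- fh_fit(de, aux, covariates = character(0), include_state = FALSE)

  sae_a <- fh_mse(fit, de, aux, B = 60, seed = 5)
  sae_b <- fh_mse(fit, de, aux, B = 60, seed = 5)
  expect_identical(sae_a$mse_eta, sae_b$mse_eta)

  # balanced intercept-only: leading term of the MSE is gamma * psi
  sae <- fh_mse(fit, de, aux, B = 500, seed = 6)
  gamma <- fit$sigma2_u_hat / (fit$sigma2_u_hat + psi)
  expect_lt(abs(mean(sae$mse_eta) - gamma * psi) / (gamma * psi), 0.15)

  # intervals contain the point estimate and live in (0, 1)
  expect_true(all(sae$ci_low <= sae$theta_hat & sae$theta_hat <= sae$ci_high))
  expect_true(all(sae$ci_low > 0 & sae$ci_high < 1))

  # no area variance and vanishing sampling variance: MSE -> 0
  fit0 <- manual_fh_fit(0.5, 0, de$district_id[1:10], y = y[1:10],
                        psi = rep(1e-10, 10))
  de0 <- manual_direct(y[1:10], rep(1e-10, 10), ids = de$district_id[1:10])
  sae0 <- fh_mse(fit0, de0, manual_aux(de$district_id[1:10]), B = 60, seed = 1)
  expect_lt(max(sae0$mse_eta), 1e-6)
})

test_that("bias-corrected back-transform shifts towards one half", {
  set.seed(4)
  y <- rnorm(30, -2, 0.5)
  de <- manual_direct(y, rep(0.3, 30))
  aux <- manual_aux(de$district_id)
  fit <- fh_fit(de, aux, covariates = character(0), include_state = FALSE)
  naive <- fh_mse(fit, de, aux, B = 60, seed = 2)
  bc <- fh_mse(fit, de, aux, B = 60, seed = 2,
               backtransform = "bias_corrected")
  # E[expit(N(eta, v))] > expit(eta) when expit(eta) < 0.5
  expect_true(all(bc$theta_hat > naive$theta_hat))
  # correction agrees with direct numerical integration on one district
  v <- naive$mse_eta[1]
  num <- integrate(function(t) plogis(t) * dnorm(t, naive$eta_hat[1], sqrt(v)),
                   -Inf, Inf)$value
  expect_equal(bc$theta_hat[1], num, tolerance = 1e-6)
})
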