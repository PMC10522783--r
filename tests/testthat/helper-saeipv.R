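# Hand-built unit-square grid map, independent of the package's generator,
# used as a geometry oracle fixture. Cell (ix, iy) has id G<k> with
# k = (iy - 1) * nx + ix.
grid_map <- function(nx, ny, state_fun = function(ix, iy) "S1") {
  districts <- list()
  k <- 0
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1
    districts[[k]] <- list(
      district_id = sprintf("G%02d", k),
      state_id = state_fun(ix, iy),
      ring = rbind(c(ix - 1, iy - 1), c(ix, iy - 1),
                   c(ix, iy), c(ix - 1, iy)))
  }
  district_geography(districts)
}

# spatial_weights built by hand from an adjacency list (row-standardised)
manual_weights <- function(adj) {
  ids <- names(adj)
  w <- lapply(adj, function(nb)
    if (length(nb) == 0) numeric(0) else rep(1 / length(nb), length(nb)))
  structure(list(ids = ids, neighbours = adj, weights = w,
                 row_standardized = TRUE,
                 neighbourless_ids = ids[lengths(adj) == 0]),
            class = "spatial_weights")
}

# a minimal fitted-model object for prediction arithmetic checks
manual_fh_fit <- function(beta0, sigma2_u, district_id, y, psi,
                          outcome = "y") {
  structure(list(outcome = outcome,
                 beta_hat = c(`(Intercept)` = beta0),
                 se_beta = c(`(Intercept)` = NA_real_),
                 sigma2_u_hat = sigma2_u, loglik = NA_real_,
                 n_iterations = 0L, converged = TRUE, boundary = FALSE,
                 method = "ML", covariates = character(0),
                 include_state = FALSE, district_id = district_id,
                 y = y, X = matrix(1, length(y), 1,
                                   dimnames = list(NULL, "(Intercept)")),
                 psi = psi),
            class = "fh_fit")
}

# direct-estimates table crafted from logit-scale values (for model tests)
manual_direct <- function(y_logit, psi, ids = sprintf("D%03d", seq_along(y_logit)),
                          outcome = "y") {
  p <- plogis(y_logit)
  data.frame(district_id = ids, outcome = outcome,
             n_respondents = NA_integer_, n_psus = NA_integer_,
             p_hat = p, var_p = psi * (p * (1 - p))^2,
             se = sqrt(psi) * p * (1 - p),
             cv = sqrt(psi) * (1 - p), psi = psi,
             ci_low = NA_real_, ci_high = NA_real_, usable = TRUE,
             stringsAsFactors = FALSE)
}

# intercept-only auxiliary table (no covariates)
manual_aux <- function(ids, state = "S1") {
  data.frame(district_id = ids, state_id = state, stringsAsFactors = FALSE)
}

# The reference Monte-Carlo experiment shared by several acceptance
# properties: 50 replicates of the 100-district design with ~150 expected
# respondents per district. Computed once per test run.
.acc_cache <- new.env(parent = emptyenv())
acceptance_recovery <- function() {
  if (is.null(.acc_cache$rec)) {
    cfg <- synth_config(n_states = 5, districts_per_state = 20, seed = 1)
    .acc_cache$rec <- recovery_experiment(cfg, n_replicates = 50,
                                          bootstrap_B = 100)
  }
  .acc_cache$rec
}
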