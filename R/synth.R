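## Synthetic-data generator: geography, spatially autocorrelated auxiliary
## covariates, true district prevalences under the logit-Normal area-level
## model, and a two-stage weighted survey sample with a domestic-violence
## style household subsample. Truth is retained so that estimators can be
## validated against it.

## Census-style auxiliary covariate names (all proportion-scaled)
AUX_NAME_POOL <- c(
  "sc_st_share", "female_literacy", "literacy_sex_gap",
  "female_work_participation", "work_sex_gap", "female_head_share",
  "hindu_share", "male_outmigration", "urban_share", "low_ses_share",
  "male_birth_share", "early_marriage_share")

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator with validation. The defaults encode
#' the reference experiment used throughout the package tests: a moderate
#' multi-state map, ten primary sampling units (PSUs) of one hundred
#' households per district, the 15% household subsample with one eligible
#' respondent per selected household that domestic-violence survey modules
#' use, a logit-scale linking model in two census-style covariates, and an
#' area-effect standard deviation of 0.3.
#'
#' @param n_states number of states.
#' @param districts_per_state districts per state (scalar or per-state
#'   vector).
#' @param psus_per_district PSUs (survey clusters) per district.
#' @param households_per_psu households listed per PSU.
#' @param dv_subsample_fraction fraction of households selected for the
#'   module, in (0, 1]; one respondent per selected household.
#' @param beta_true logit-scale coefficient vector (intercept first) of the
#'   linking model.
#' @param truth_covariates names of auxiliary columns entering the linking
#'   model; length must be `length(beta_true) - 1`.
#' @param sigma_u_true standard deviation (logit scale) of district random
#'   effects; non-negative.
#' @param spatial_range correlation length (map units) of the Gaussian
#'   random fields behind the covariates; larger values give smoother,
#'   spatially clustered covariates (and hence clustered prevalence).
#' @param weight_dispersion coefficient of variation of design weights
#'   within a district (0 gives constant weights).
#' @param psu_effect_sd standard deviation of the log of the mild
#'   multiplicative PSU-level effect on prevalence (0 disables it).
#' @param n_covariates number of auxiliary covariates to generate.
#' @param outcomes named numeric vector of logit-scale intercept shifts, one
#'   outcome column per entry (default: physical / emotional / sexual IPV at
#'   decreasing prevalence).
#' @param seed master seed; every downstream stage derives its stream from
#'   it, so identical configurations reproduce identical outputs.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_states = 6,
                         districts_per_state = 6,
                         psus_per_district = 10,
                         households_per_psu = 100,
                         dv_subsample_fraction = 0.15,
                         beta_true = c(-1.2, 0.8, -0.5),
                         truth_covariates = c("sc_st_share", "female_literacy"),
                         sigma_u_true = 0.3,
                         spatial_range = 2,
                         weight_dispersion = 0.3,
                         psu_effect_sd = 0.15,
                         n_covariates = 4,
                         outcomes = c(y_physical = 0, y_emotional = -0.9,
                                      y_sexual = -1.8),
                         seed = 1L) {
  if (n_states < 1) stop_config("n_states must be >= 1")
  if (any(districts_per_state < 1)) stop_config("districts_per_state must be >= 1")
  if (psus_per_district < 1 || households_per_psu < 1)
    stop_config("PSU and household counts must be >= 1")
  if (dv_subsample_fraction <= 0 || dv_subsample_fraction > 1)
    stop_config("dv_subsample_fraction must be in (0, 1]")
  if (sigma_u_true < 0) stop_config("sigma_u_true must be >= 0")
  if (spatial_range <= 0) stop_config("spatial_range must be > 0")
  if (weight_dispersion < 0) stop_config("weight_dispersion must be >= 0")
  if (length(beta_true) != length(truth_covariates) + 1)
    stop_config("beta_true must have length(truth_covariates) + 1 entries")
  if (n_covariates < length(truth_covariates))
    stop_config("n_covariates must cover truth_covariates")
  structure(list(n_states = as.integer(n_states),
                 districts_per_state = as.integer(districts_per_state),
                 psus_per_district = as.integer(psus_per_district),
                 households_per_psu = as.integer(households_per_psu),
                 dv_subsample_fraction = dv_subsample_fraction,
                 beta_true = beta_true,
                 truth_covariates = truth_covariates,
                 sigma_u_true = sigma_u_true,
                 spatial_range = spatial_range,
                 weight_dispersion = weight_dispersion,
                 psu_effect_sd = psu_effect_sd,
                 n_covariates = as.integer(n_covariates),
                 outcomes = outcomes,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic district map
#'
#' Tiles a rectangle with districts arranged in rows; row heights and cell
#' boundaries are mildly jittered so polygons are irregular rectangles, yet
#' the union is exactly the bounding rectangle and the queen-contiguity
#' graph is connected. States are contiguous blocks of districts in
#' boustrophedon (snake) order, so every state is connected and interstate
#' borders are well defined.
#'
#' @param n_states number of states.
#' @param districts_per_state districts per state (scalar or per-state
#'   vector).
#' @param seed integer seed (controls the boundary jitter).
#' @return A `district_geography`.
#' @export
generate_geography <- function(n_states, districts_per_state, seed = 1L) {
  if (n_states < 1 || any(districts_per_state < 1))
    stop_config("state and district counts must be positive")
  per_state <- if (length(districts_per_state) == 1) {
    rep(districts_per_state, n_states)
  } else {
    if (length(districts_per_state) != n_states)
      stop_config("districts_per_state must be scalar or length n_states")
    districts_per_state
  }
  D <- sum(per_state)
  if (D < 4) stop_config("total number of districts must be >= 4")
  nr <- max(1L, as.integer(round(sqrt(D))))
  base <- D %/% nr; extra <- D %% nr
  row_counts <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))
  row_counts <- row_counts[row_counts > 0]
  nr <- length(row_counts)
  W <- max(row_counts)
  with_seed(seed, {
    # jittered horizontal bands
    ybreaks <- seq(0, nr, length.out = nr + 1)
    if (nr > 1)
      ybreaks[2:nr] <- ybreaks[2:nr] + stats::runif(nr - 1, -0.15, 0.15)
    rows <- lapply(seq_len(nr), function(r) {
      k <- row_counts[r]
      xb <- seq(0, W, length.out = k + 1)
      if (k > 1)
        xb[2:k] <- xb[2:k] + stats::runif(k - 1, -0.15, 0.15) * (W / k)
      xb
    })
    NULL
  })
  # districts in snake order; states as consecutive blocks
  state_of_idx <- rep(paste0("S", seq_len(n_states)), per_state)
  districts <- vector("list", D)
  idx <- 0L
  for (r in seq_len(nr)) {
    k <- row_counts[r]
    cols <- if (r %% 2 == 1) seq_len(k) else rev(seq_len(k))
    for (cc in cols) {
      idx <- idx + 1L
      xb <- rows[[r]]
      ring <- rbind(c(xb[cc], ybreaks[r]), c(xb[cc + 1], ybreaks[r]),
                    c(xb[cc + 1], ybreaks[r + 1]), c(xb[cc], ybreaks[r + 1]))
      districts[[idx]] <- list(district_id = sprintf("D%03d", idx),
                               state_id = state_of_idx[idx],
                               ring = ring)
    }
  }
  district_geography(districts)
}

## Gaussian random field values at district centroids with exponential
## correlation exp(-d / range); small nugget keeps the Cholesky stable.
grf_draws <- function(centroids, spatial_range, k) {
  d <- as.matrix(stats::dist(centroids))
  S <- exp(-d / spatial_range) + diag(1e-6, nrow(d))
  L <- t(chol(S))
  sapply(seq_len(k), function(j) as.numeric(L %*% stats::rnorm(nrow(d))))
}

#' Generate district auxiliary covariates
#'
#' Each covariate is a proportion in \[0, 1\] obtained by the probability
#' transform of a smooth Gaussian random field over district centroids,
#' with correlation decaying exponentially at scale `spatial_range`. A
#' border proximity factor column (`bpf`) is appended via [compute_bpf()].
#' The covariate matrix (with intercept) is checked for full column rank;
#' degenerate draws are retried with a perturbed seed (at most 5 attempts).
#'
#' @param geography a `district_geography`.
#' @param spatial_range positive correlation length in map units.
#' @param seed integer seed.
#' @param n_covariates number of covariates (named from a census-style
#'   pool: caste/tribe share, female literacy and its sex gap, workforce
#'   participation, household headship, ...).
#' @return data.frame with `district_id`, `state_id`, the covariates and
#'   `bpf`.
#' @export
generate_auxiliary <- function(geography, spatial_range, seed = 1L,
                               n_covariates = 4) {
  if (spatial_range <= 0) stop_config("spatial_range must be > 0")
  stopifnot(inherits(geography, "district_geography"))
  cn <- if (n_covariates <= length(AUX_NAME_POOL)) {
    AUX_NAME_POOL[seq_len(n_covariates)]
  } else {
    c(AUX_NAME_POOL,
      paste0("aux_extra_", seq_len(n_covariates - length(AUX_NAME_POOL))))
  }
  centroids <- t(vapply(geography$districts,
                        function(d) polygon_centroid(d$ring), c(0, 0)))
  for (attempt in seq_len(5)) {
    Z <- with_seed(derive_seed(seed, attempt - 1),
                   grf_draws(centroids, spatial_range, n_covariates))
    X <- stats::pnorm(Z)
    if (qr(cbind(1, X))$rank == n_covariates + 1) {
      colnames(X) <- cn
      # single-state maps have no interstate border; measure BPF from the
      # study-area outline instead
      single_state <- length(unique(state_of(geography))) == 1
      bpf <- compute_bpf(geography, include_outer_frame = single_state)
      aux <- data.frame(district_id = district_ids(geography),
                        state_id = state_of(geography),
                        X, stringsAsFactors = FALSE)
      aux$bpf <- bpf$bpf[match(aux$district_id, bpf$district_id)]
      return(aux)
    }
  }
  stop_config("covariate matrix rank-deficient after 5 attempts")
}

## auxiliary covariate columns (everything except the identifiers)
aux_covariate_names <- function(aux) {
  setdiff(names(aux), c("district_id", "state_id"))
}

#' Generate true district prevalences under the linking model
#'
#' Draws district effects u_d ~ N(0, sigma_u^2) and sets
#' logit(theta_d) = x_d' beta + u_d, the logit-Normal area-level model the
#' estimation stage assumes.
#'
#' @param aux auxiliary table from [generate_auxiliary()].
#' @param beta_true coefficient vector, intercept first.
#' @param sigma_u_true non-negative area-effect SD (logit scale).
#' @param seed integer seed.
#' @param covariates covariate columns entering the model (default: all
#'   covariate columns of `aux`, including `bpf`); `length(beta_true)` must
#'   equal `length(covariates) + 1`.
#' @return data.frame of class `true_params` with `district_id`,
#'   `theta_true`, `u_true`; `beta_true`, `sigma_u_true` and `covariates`
#'   kept as attributes.
#' @export
generate_truth <- function(aux, beta_true, sigma_u_true, seed = 1L,
                           covariates = NULL) {
  if (is.null(covariates)) covariates <- aux_covariate_names(aux)
  if (!all(covariates %in% names(aux)))
    stop_config("covariates missing from aux: %s",
                paste(setdiff(covariates, names(aux)), collapse = ", "))
  if (length(beta_true) != length(covariates) + 1)
    stop_config("beta_true has length %d but 1 + %d covariates are used",
                length(beta_true), length(covariates))
  if (sigma_u_true < 0) stop_config("sigma_u_true must be >= 0")
  X <- cbind(1, as.matrix(aux[covariates]))
  u <- with_seed(seed, stats::rnorm(nrow(aux), 0, sigma_u_true))
  eta <- as.numeric(X %*% beta_true) + u
  out <- data.frame(district_id = aux$district_id,
                    theta_true = expit(eta), u_true = u,
                    stringsAsFactors = FALSE)
  structure(out, beta_true = beta_true, sigma_u_true = sigma_u_true,
            covariates = covariates, class = c("true_params", "data.frame"))
}

#' Draw a two-stage weighted survey sample
#'
#' Emulates the survey design behind a domestic-violence module: within
#' each district, `psus_per_district` PSUs of `households_per_psu`
#' households; each household is independently selected with probability
#' `dv_subsample_fraction` and contributes exactly one respondent. The
#' respondent's outcome is Bernoulli with probability
#' `theta_d * m_psu`, where `m_psu = exp(N(0, psu_effect_sd^2))` is a mild
#' multiplicative PSU effect (clipped to keep the probability inside
#' (0, 1)) that induces realistic design effects while leaving `theta_d`
#' the exact district-level estimand. Design weights are log-normal with
#' coefficient of variation `weight_dispersion`, rescaled to mean 1 within
#' each district.
#'
#' @param truth a `true_params` object, or a named list of them (one per
#'   outcome; all must share the sampling frame). With a list, one outcome
#'   column per name is emitted, sharing households, weights and PSU
#'   effects across outcomes as a single interviewed woman would.
#' @param config a `synth_config`.
#' @param seed optional integer seed; defaults to a stream derived from
#'   `config$seed`.
#' @return data.frame with `respondent_id`, `district_id`, `psu_id`,
#'   `weight` and one outcome column (`y`, or `y_<name>` per truth entry).
#' @export
sample_survey <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  truths <- if (inherits(truth, "true_params")) list(y = truth) else truth
  stopifnot(length(truths) >= 1)
  ids <- truths[[1]]$district_id
  for (tt in truths) stopifnot(identical(tt$district_id, ids))
  exp_resp <- config$psus_per_district * config$households_per_psu *
    config$dv_subsample_fraction
  if (exp_resp < 2)
    stop_config("expected respondents per district (%.2f) < 2; variance estimation impossible",
                exp_resp)
  if (is.null(seed)) seed <- derive_seed(config$seed, 4)
  theta <- do.call(cbind, lapply(truths, `[[`, "theta_true"))
  with_seed(seed, {
    recs <- vector("list", length(ids))
    for (d in seq_along(ids)) {
      psu_rows <- vector("list", config$psus_per_district)
      for (p in seq_len(config$psus_per_district)) {
        m_psu <- exp(stats::rnorm(1, 0, config$psu_effect_sd))
        prob <- pmin(pmax(theta[d, ] * m_psu, 1e-9), 1 - 1e-9)
        sel <- stats::rbinom(config$households_per_psu, 1,
                             config$dv_subsample_fraction) == 1
        n_sel <- sum(sel)
        if (n_sel == 0) next
        y <- matrix(stats::rbinom(n_sel * length(prob), 1,
                                  rep(prob, each = n_sel)),
                    nrow = n_sel)
        psu_rows[[p]] <- data.frame(
          district_id = ids[d],
          psu_id = sprintf("%s_P%02d", ids[d], p),
          y, stringsAsFactors = FALSE)
      }
      dd <- do.call(rbind, psu_rows)
      if (is.null(dd)) next
      w <- if (config$weight_dispersion == 0) {
        rep(1, nrow(dd))
      } else {
        s2 <- log(1 + config$weight_dispersion^2)
        w0 <- stats::rlnorm(nrow(dd), -s2 / 2, sqrt(s2))
        w0 / mean(w0)
      }
      dd$weight <- w
      recs[[d]] <- dd
    }
    out <- do.call(rbind, recs)
    names(out)[seq_along(truths) + 2] <- names(truths)
    out <- data.frame(respondent_id = sprintf("R%06d", seq_len(nrow(out))),
                      out, stringsAsFactors = FALSE)
    out[c("respondent_id", "district_id", "psu_id", "weight", names(truths))]
  })
}
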