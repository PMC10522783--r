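test_that("generated geography tiles a rectangle with contiguous states", {
  # single state: all districts labelled with it, interiors disjoint
  g1 <- generate_geography(1, 4, seed = 1)
  expect_length(g1$districts, 4)
  expect_true(all(vapply(g1$districts, `[[`, "", "state_id") == "S1"))
  rects <- lapply(g1$districts, function(d) {
    r <- d$ring
    c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
  })
  for (i in 1:3) for (j in (i + 1):4) {
    a <- rects[[i]]; b <- rects[[j]]
    ov <- max(0, min(a[3], b[3]) - max(a[1], b[1])) *
      max(0, min(a[4], b[4]) - max(a[2], b[2]))
    expect_lt(ov, 1e-9)
  }

  # tiling conserves area
  g2 <- generate_geography(2, 2, seed = 7)
  areas <- vapply(g2$districts, function(d) saeipv:::polygon_area(d$ring), 0)
  bb <- saeipv:::geo_bbox(g2)
  expect_equal(sum(areas),
               (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # queen-contiguity graph is connected (breadth-first traversal)
  g3 <- generate_geography(3, 4, seed = 11)
  w <- queen_weights(g3)
  seen <- w$ids[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(w$neighbours[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  expect_setequal(seen, w$ids)

  expect_error(generate_geography(0, 4), "positive")
  expect_error(generate_geography(1, 3), ">= 4")
})

test_that("auxiliary covariates are proportion-scaled, full rank, and carry the requested spatial structure", {
  geo <- generate_geography(3, 12, seed = 5)
  w <- queen_weights(geo)

  # independence limit: tiny range leaves each covariate inside the
  # wide permutation band of the no-autocorrelation null
  aux0 <- generate_auxiliary(geo, spatial_range = 1e-6, seed = 1,
                             n_covariates = 3)
  cov_cols <- setdiff(names(aux0), c("district_id", "state_id", "bpf"))
  for (cc in cov_cols) {
    v <- setNames(aux0[[cc]], aux0$district_id)
    expect_true(all(v >= 0 & v <= 1))
    gt <- global_moran_test(v, w, n_perm = 399, seed = 2)
    band <- quantile(gt$I_perm, c(0.005, 0.995))
    expect_gt(gt$I_obs, band[1])
    expect_lt(gt$I_obs, band[2])
  }

  # strong autocorrelation: beyond the 97.5% null quantile in >= 4/5 seeds
  bb <- saeipv:::geo_bbox(geo)
  diam <- sqrt((bb["xmax"] - bb["xmin"])^2 + (bb["ymax"] - bb["ymin"])^2)
  hits <- 0
  for (s in 1:5) {
    aux1 <- generate_auxiliary(geo, spatial_range = diam, seed = 10 + s,
                               n_covariates = 2)
    ok <- vapply(setdiff(names(aux1), c("district_id", "state_id", "bpf")),
                 function(cc) {
                   v <- setNames(aux1[[cc]], aux1$district_id)
                   gt <- global_moran_test(v, w, n_perm = 199, seed = 3)
                   gt$I_obs > quantile(gt$I_perm, 0.975)
                 }, TRUE)
    hits <- hits + all(ok)
  }
  expect_gte(hits, 4)

  # covariate matrix has full column rank with intercept
  X <- cbind(1, as.matrix(aux0[setdiff(names(aux0),
                                       c("district_id", "state_id"))]))
  expect_equal(qr(X)$rank, ncol(X))

  expect_error(generate_auxiliary(geo, spatial_range = 0), "spatial_range")
})

test_that("true prevalences respect the linking model exactly", {
  geo <- generate_geography(2, 4, seed = 3)
  aux <- generate_auxiliary(geo, 2, seed = 4, n_covariates = 2)
  cn <- c("sc_st_share", "female_literacy")

  # sigma_u = 0, beta = 0 -> theta = 0.5 everywhere
  t0 <- generate_truth(aux, c(0, 0, 0), 0, seed = 1, covariates = cn)
  expect_equal(t0$theta_true, rep(0.5, 8))

  # closed form with a constant unit covariate
  aux1 <- aux
  aux1$ones <- 1
  t1 <- generate_truth(aux1, c(0, 1), 0, seed = 1, covariates = "ones")
  expect_equal(t1$theta_true, rep(0.7310586, 8), tolerance = 1e-6)

  # identity logit(theta) - u = X beta holds for every district
  tr <- generate_truth(aux, c(-1, 0.6, -0.4), 0.4, seed = 9, covariates = cn)
  X <- cbind(1, as.matrix(aux[cn]))
  expect_equal(qlogis(tr$theta_true) - tr$u_true,
               as.numeric(X %*% c(-1, 0.6, -0.4)), tolerance = 1e-12)

  # Monte-Carlo scale of the area effects at sigma_u = 0.5
  geo2 <- generate_geography(10, 20, seed = 6)
  aux2 <- generate_auxiliary(geo2, 2, seed = 7, n_covariates = 2)
  ok <- 0
  for (s in 1:10) {
    tt <- generate_truth(aux2, c(-1, 0, 0), 0.5, seed = 20 + s,
                         covariates = cn)
    sdv <- sd(qlogis(tt$theta_true))
    ok <- ok + (sdv >= 0.35 && sdv <= 0.65)
  }
  expect_gte(ok, 9)

  expect_error(generate_truth(aux, c(0, 0), 0.3, covariates = cn),
               "length")
})

test_that("survey sampling respects the two-stage subsampled design", {
  geo <- generate_geography(1, 4, seed = 2)
  aux <- generate_auxiliary(geo, 2, seed = 2, n_covariates = 2)
  cn <- c("sc_st_share", "female_literacy")
  truth_half <- generate_truth(aux, c(0, 0, 0), 0, seed = 1, covariates = cn)

  # full take-up, no weight noise, no PSU effect: pooled mean near theta
  cfg1 <- synth_config(n_states = 1, districts_per_state = 4,
                       psus_per_district = 10, households_per_psu = 250,
                       dv_subsample_fraction = 1, weight_dispersion = 0,
                       psu_effect_sd = 0, seed = 1)
  ok <- 0
  for (s in 1:10) {
    sv <- sample_survey(truth_half, cfg1, seed = 100 + s)
    expect_equal(nrow(sv), 10000)
    expect_true(all(sv$weight == 1))
    m <- mean(sv$y)
    ok <- ok + (m >= 0.49 && m <= 0.51)
  }
  expect_gte(ok, 9)

  # binomial respondent counts under the 15% household subsample
  cfg2 <- synth_config(n_states = 1, districts_per_state = 4,
                       psus_per_district = 10, households_per_psu = 100,
                       dv_subsample_fraction = 0.15, seed = 1)
  band <- 3 * sqrt(150 * 0.85)
  ok <- 0
  for (s in 1:10) {
    sv <- sample_survey(truth_half, cfg2, seed = 200 + s)
    counts <- table(sv$district_id)
    ok <- ok + all(abs(counts - 150) <= band)
    # at most one respondent per household
    expect_lte(max(table(sv$psu_id)), 100)
  }
  expect_gte(ok, 9)

  # determinism: identical config and seed give identical tables
  sv_a <- sample_survey(truth_half, cfg2, seed = 77)
  sv_b <- sample_survey(truth_half, cfg2, seed = 77)
  expect_identical(sv_a, sv_b)

  # too few expected respondents is a configuration error
  expect_error(
    sample_survey(truth_half,
                  synth_config(n_states = 1, districts_per_state = 4,
                               psus_per_district = 1, households_per_psu = 10,
                               dv_subsample_fraction = 0.1, seed = 1)),
    "variance")
})

test_that("config validation rejects out-of-range generator settings", {
  expect_error(synth_config(dv_subsample_fraction = 0), "dv_subsample")
  expect_error(synth_config(dv_subsample_fraction = 1.2), "dv_subsample")
  expect_error(synth_config(sigma_u_true = -0.1), "sigma_u")
  expect_error(synth_config(spatial_range = 0), "spatial_range")
  expect_error(synth_config(beta_true = c(0, 1)), "beta_true")
})
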