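## Local indicators of spatial association (LISA): local Moran's I with
## conditional-permutation pseudo p-values and hotspot/coldspot/outlier
## classification, following the conventions of the standard desktop LISA
## tool (999 permutations, one-sided tail matching the statistic's sign,
## alpha 0.05, no multiple-testing correction by default).

#' Local Moran's I with conditional-permutation inference
#'
#' Values are standardised with the population SD over districts that have
#' neighbours and non-missing values; `I_i = z_i * sum_j w_ij z_j`. For
#' each district the permutation null holds `z_i` fixed and assigns the
#' remaining values at random (without replacement) to its neighbour
#' slots; the pseudo p-value is `(count + 1) / (n_perm + 1)` on the
#' one-sided tail matching the sign of the observed `I_i`. Significant
#' districts are classified by the signs of `z_i` and the spatial lag into
#' high-high, low-low, high-low, low-high; others are not-significant.
#' Neighbourless districts have undefined `I_i` and category
#' "neighbourless".
#'
#' @param values named numeric vector (names = district ids matching
#'   `weights$ids`).
#' @param weights a `spatial_weights` object (row-standardised).
#' @param n_perm number of conditional permutations (>= 99).
#' @param alpha significance level for classification.
#' @param seed integer seed (same seed reproduces the p-value vector).
#' @param fdr apply a Benjamini-Hochberg correction across districts
#'   before classification (off by default, matching the desktop tool).
#' @return data.frame of class `lisa_result` with `district_id`, `value`,
#'   `z_i`, `lag_z`, `I_i`, `p_pseudo`, `category`, plus a `counts`
#'   attribute tabulating categories.
#' @export
local_moran <- function(values, weights, n_perm = 999, alpha = 0.05,
                        seed = 1L, fdr = FALSE) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (n_perm < 99) stop_config("n_perm must be >= 99")
  ids <- weights$ids
  x <- values[ids]
  if (is.null(names(values))) stop_config("values must be named by district id")
  has_nb <- !(ids %in% weights$neighbourless_ids)
  missing_v <- is.na(x)
  use <- has_nb & !missing_v
  if (sum(use) < 3) stop_config("fewer than 3 usable districts")
  xm <- mean(x[use])
  s <- sqrt(mean((x[use] - xm)^2))
  if (s == 0) stop_config("all values identical; local Moran undefined")
  z <- (x - xm) / s
  n_use <- sum(use)
  lag_z <- rep(NA_real_, length(ids))
  I <- rep(NA_real_, length(ids))
  p <- rep(NA_real_, length(ids))
  category <- rep("neighbourless", length(ids))
  with_seed(seed, {
    for (i in seq_along(ids)) {
      if (!use[i]) {
        if (missing_v[i] && has_nb[i]) category[i] <- NA_character_
        next
      }
      nb <- weights$neighbours[[ids[i]]]
      wv <- weights$weights[[ids[i]]]
      keep <- nb %in% ids[use]
      if (!any(keep)) { category[i] <- "neighbourless"; next }
      nb <- nb[keep]; wv <- wv[keep]
      lag_z[i] <- sum(wv * z[nb])
      I[i] <- z[i] * lag_z[i]
      others <- z[setdiff(ids[use], ids[i])]
      k <- length(nb)
      Istar <- vapply(seq_len(n_perm), function(b) {
        z[i] * sum(wv * others[sample.int(length(others), k)])
      }, 0)
      hits <- if (I[i] >= 0) sum(Istar >= I[i]) else sum(Istar <= I[i])
      p[i] <- (hits + 1) / (n_perm + 1)
    }
  })
  p_cls <- p
  if (fdr) p_cls <- stats::p.adjust(p, method = "BH")
  for (i in seq_along(ids)) {
    if (!use[i] || is.na(I[i])) next
    category[i] <- if (!is.na(p_cls[i]) && p_cls[i] <= alpha) {
      if (z[i] >= 0 && lag_z[i] >= 0) "high-high"
      else if (z[i] < 0 && lag_z[i] < 0) "low-low"
      else if (z[i] >= 0) "high-low"
      else "low-high"
    } else "not-significant"
  }
  out <- data.frame(district_id = ids, value = unname(x), z_i = unname(z),
                    lag_z = lag_z, I_i = I, p_pseudo = p,
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(
    category, levels = c("high-high", "low-low", "high-low", "low-high",
                         "not-significant", "neighbourless")))
  class(out) <- c("lisa_result", "data.frame")
  out
}

## all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Exact conditional-permutation p-value on tiny graphs
#'
#' Enumerates every assignment of the other n-1 standardised values to the
#' focal district's neighbour slots and returns the exact one-sided tail
#' probability of the observed local Moran statistic. Used as an
#' enumeration oracle for the Monte-Carlo permutation engine; refuses
#' n > 8.
#'
#' @param values named numeric vector.
#' @param weights a `spatial_weights` object.
#' @param district_id the focal district.
#' @return list with `I_i` and `p_exact`.
#' @export
exact_permutation_check <- function(values, weights, district_id) {
  ids <- weights$ids
  n <- length(ids)
  if (n > 8) stop_config("exact enumeration limited to n <= 8")
  x <- values[ids]
  has_nb <- !(ids %in% weights$neighbourless_ids)
  xm <- mean(x[has_nb]); s <- sqrt(mean((x[has_nb] - xm)^2))
  if (s == 0) stop_config("all values identical")
  z <- (x - xm) / s
  i <- match(district_id, ids)
  if (is.na(i) || !has_nb[i]) stop_config("district %s has no neighbours",
                                          district_id)
  nb <- weights$neighbours[[district_id]]
  wv <- weights$weights[[district_id]]
  others <- z[setdiff(ids[has_nb], district_id)]
  k <- length(nb)
  I_obs <- z[i] * sum(wv * z[nb])
  # enumerate ordered k-tuples of the others: combinations x slot orders
  combs <- utils::combn(length(others), k)
  slot_perms <- all_perms(k)
  hits <- 0; total <- 0
  for (cidx in seq_len(ncol(combs))) {
    vals <- others[combs[, cidx]]
    for (pidx in seq_len(nrow(slot_perms))) {
      Istar <- z[i] * sum(wv * vals[slot_perms[pidx, ]])
      hits <- hits + (if (I_obs >= 0) Istar >= I_obs - 1e-12
                      else Istar <= I_obs + 1e-12)
      total <- total + 1
    }
  }
  list(I_i = unname(I_obs), p_exact = unname(hits / total))
}

#' Global Moran's I
#'
#' Computed directly from its definition with row-standardised weights
#' over districts that have neighbours; equals the mean of the local
#' statistics from [local_moran()].
#'
#' @param values named numeric vector.
#' @param weights a `spatial_weights` object.
#' @return scalar global Moran's I.
#' @export
global_moran <- function(values, weights) {
  ids <- weights$ids
  has_nb <- !(ids %in% weights$neighbourless_ids)
  x <- values[ids][has_nb]
  xm <- mean(x)
  z <- (x - xm)
  S0 <- sum(unlist(weights$weights[ids[has_nb]]))
  num <- 0
  for (id in ids[has_nb]) {
    nb <- weights$neighbours[[id]]
    wv <- weights$weights[[id]]
    keep <- nb %in% ids[has_nb]
    num <- num + (x[id] - xm) * sum(wv[keep] * (values[nb[keep]] - xm))
  }
  unname((length(z) / S0) * num / sum(z^2))
}

#' Global Moran permutation test
#'
#' Monte-Carlo permutation null for global Moran's I; returns the observed
#' statistic, the permutation draws and a two-sided pseudo p-value. Used
#' to check the spatial structure of generated covariates.
#'
#' @param values named numeric vector.
#' @param weights a `spatial_weights` object.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `I_obs`, `I_perm`, `p_pseudo`.
#' @export
global_moran_test <- function(values, weights, n_perm = 999, seed = 1L) {
  ids <- weights$ids
  has_nb <- !(ids %in% weights$neighbourless_ids)
  I_obs <- global_moran(values, weights)
  v <- values[ids]
  with_seed(seed, {
    I_perm <- vapply(seq_len(n_perm), function(b) {
      vp <- v
      vp[has_nb] <- sample(v[has_nb])
      global_moran(vp, weights)
    }, 0)
  })
  hits <- sum(abs(I_perm - mean(I_perm)) >= abs(I_obs - mean(I_perm)))
  list(I_obs = I_obs, I_perm = I_perm,
       p_pseudo = (hits + 1) / (n_perm + 1))
}
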