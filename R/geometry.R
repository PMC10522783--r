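## Planar polygon geometry: queen contiguity weights and the border
## proximity factor (BPF). District maps are collections of simple planar
## polygons carrying district_id and state_id; shared borders between
## districts must be colinear segment overlaps (true of any well-formed
## administrative tiling and of the synthetic grid maps in this package).

#' Construct a district geography object
#'
#' @param districts list of entries, each with `district_id`, `state_id` and
#'   `ring`, an n x 2 numeric matrix of polygon vertices (open ring: the
#'   first vertex is not repeated at the end).
#' @return An object of class `district_geography`.
#' @export
district_geography <- function(districts) {
  ids <- vapply(districts, function(d) as.character(d$district_id), "")
  if (anyDuplicated(ids))
    stop_config("duplicate district ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (d in districts) {
    r <- d$ring
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      stop_config("district %s: ring must be an n x 2 matrix with n >= 3",
                  d$district_id)
    if (ring_self_intersects(r))
      stop_config("district %s: polygon is self-intersecting", d$district_id)
  }
  names(districts) <- ids
  structure(list(districts = districts), class = "district_geography")
}

#' @export
print.district_geography <- function(x, ...) {
  st <- vapply(x$districts, function(d) as.character(d$state_id), "")
  cat(sprintf("district_geography: %d districts in %d states\n",
              length(x$districts), length(unique(st))))
  invisible(x)
}

district_ids <- function(geo) names(geo$districts)
state_of <- function(geo) {
  vapply(geo$districts, function(d) as.character(d$state_id), "")
}

geo_bbox <- function(geo) {
  xy <- do.call(rbind, lapply(geo$districts, `[[`, "ring"))
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

geo_tol <- function(geo) {
  bb <- geo_bbox(geo)
  1e-9 * max(1, bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

## edges as matrix [x1 y1 x2 y2], one row per edge of the closed ring
ring_edges <- function(ring) {
  n <- nrow(ring)
  cbind(ring, ring[c(2:n, 1), , drop = FALSE])
}

## squared distance from points (px, py) to one segment
point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

## minimum distance from a set of points to the nearest of many segments
min_dist_to_segments <- function(pts, segs) {
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(segs))) {
    d2 <- pmin(d2, point_seg_dist2(pts[, 1], pts[, 2],
                                   segs[k, 1], segs[k, 2],
                                   segs[k, 3], segs[k, 4]))
  }
  sqrt(d2)
}

seg_cross <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

## do segments p1-p2 and p3-p4 properly intersect (crossing interiors)?
segs_properly_intersect <- function(p1, p2, p3, p4) {
  d1 <- seg_cross(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- seg_cross(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- seg_cross(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- seg_cross(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

ring_self_intersects <- function(ring) {
  e <- ring_edges(ring)
  n <- nrow(e)
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segs_properly_intersect(e[i, 1:2], e[i, 3:4], e[j, 1:2], e[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

## minimum distance between two segments (0 if they intersect)
seg_seg_dist <- function(a, b) {
  if (segs_properly_intersect(a[1:2], a[3:4], b[1:2], b[3:4])) return(0)
  sqrt(min(point_seg_dist2(a[1], a[2], b[1], b[2], b[3], b[4]),
           point_seg_dist2(a[3], a[4], b[1], b[2], b[3], b[4]),
           point_seg_dist2(b[1], b[2], a[1], a[2], a[3], a[4]),
           point_seg_dist2(b[3], b[4], a[1], a[2], a[3], a[4])))
}

## Colinear overlap of segment b on segment a, as a parameter interval
## [t0, t1] along a (NULL if not colinear or overlap has zero length).
colinear_overlap <- function(a, b, tol) {
  dx <- a[3] - a[1]; dy <- a[4] - a[2]
  len <- sqrt(dx * dx + dy * dy)
  if (len < tol) return(NULL)
  # both endpoints of b must lie on the line through a
  h1 <- abs((b[1] - a[1]) * dy - (b[2] - a[2]) * dx) / len
  h2 <- abs((b[3] - a[1]) * dy - (b[4] - a[2]) * dx) / len
  if (h1 > tol || h2 > tol) return(NULL)
  t1 <- ((b[1] - a[1]) * dx + (b[2] - a[2]) * dy) / (len * len)
  t2 <- ((b[3] - a[1]) * dx + (b[4] - a[2]) * dy) / (len * len)
  lo <- max(0, min(t1, t2)); hi <- min(1, max(t1, t2))
  if ((hi - lo) * len <= tol) return(NULL)
  c(lo, hi)
}

## point on segment a at parameter t
seg_point_at <- function(a, t) {
  c(a[1] + t * (a[3] - a[1]), a[2] + t * (a[4] - a[2]))
}

## Sample n points uniformly by arc length along a closed ring.
boundary_sample <- function(ring, n) {
  e <- ring_edges(ring)
  len <- sqrt((e[, 3] - e[, 1])^2 + (e[, 4] - e[, 2])^2)
  total <- sum(len)
  s <- (seq_len(n) - 0.5) / n * total
  cum <- cumsum(len)
  idx <- findInterval(s, c(0, cum), rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(e))
  t0 <- (s - c(0, cum)[idx]) / len[idx]
  cbind(e[idx, 1] + t0 * (e[idx, 3] - e[idx, 1]),
        e[idx, 2] + t0 * (e[idx, 4] - e[idx, 2]))
}

#' Queen-contiguity spatial weights
#'
#' Districts sharing at least one boundary point (edge segment or a single
#' vertex) are neighbours. Weights are row-standardised: each district's
#' neighbours receive weight 1/k where k is its neighbour count. Districts
#' without any neighbour are listed in `neighbourless_ids` and carry zero
#' weights; they are excluded from row standardisation.
#'
#' @param geography a `district_geography` object.
#' @return An object of class `spatial_weights`: list with `ids`,
#'   `neighbours` (named list of character vectors), `weights` (named list of
#'   numeric vectors aligned with `neighbours`), `row_standardized = TRUE`
#'   and `neighbourless_ids`.
#' @export
queen_weights <- function(geography) {
  stopifnot(inherits(geography, "district_geography"))
  ids <- district_ids(geography)
  n <- length(ids)
  tol <- geo_tol(geography)
  edges <- lapply(geography$districts, function(d) ring_edges(d$ring))
  bb <- lapply(geography$districts, function(d) {
    r <- d$ring
    c(min(r[, 1]), min(r[, 2]), max(r[, 1]), max(r[, 2]))
  })
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # bounding-box prefilter
      if (bb[[i]][1] > bb[[j]][3] + tol || bb[[j]][1] > bb[[i]][3] + tol ||
          bb[[i]][2] > bb[[j]][4] + tol || bb[[j]][2] > bb[[i]][4] + tol)
        next
      touch <- FALSE
      ei <- edges[[i]]; ej <- edges[[j]]
      for (a in seq_len(nrow(ei))) {
        for (b in seq_len(nrow(ej))) {
          if (seg_seg_dist(ei[a, ], ej[b, ]) <= tol) { touch <- TRUE; break }
        }
        if (touch) break
      }
      if (touch) {
        adj[[i]] <- c(adj[[i]], ids[j])
        adj[[j]] <- c(adj[[j]], ids[i])
      }
    }
  }
  names(adj) <- ids
  w <- lapply(adj, function(nb) {
    if (length(nb) == 0) numeric(0) else rep(1 / length(nb), length(nb))
  })
  structure(list(ids = ids, neighbours = adj, weights = w,
                 row_standardized = TRUE,
                 neighbourless_ids = ids[lengths(adj) == 0]),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d districts, %d neighbourless; mean %.2f neighbours\n",
              length(x$ids), length(x$neighbourless_ids),
              mean(lengths(x$neighbours))))
  invisible(x)
}

#' Write / read spatial weights as JSON
#'
#' @param w a `spatial_weights` object.
#' @param path file path.
#' @return `read_weights` returns a `spatial_weights` object.
#' @export
write_weights <- function(w, path) {
  obj <- list(row_standardized = w$row_standardized,
              neighbourless_ids = as.list(w$neighbourless_ids),
              districts = lapply(w$ids, function(id) {
                list(id = id,
                     neighbours = as.list(w$neighbours[[id]]),
                     weights = as.list(w$weights[[id]]))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- vapply(obj$districts, `[[`, "", "id")
  nb <- lapply(obj$districts, function(d) as.character(unlist(d$neighbours)))
  wt <- lapply(obj$districts, function(d) as.numeric(unlist(d$weights)))
  names(nb) <- ids; names(wt) <- ids
  structure(list(ids = ids, neighbours = nb, weights = wt,
                 row_standardized = isTRUE(obj$row_standardized),
                 neighbourless_ids = as.character(unlist(obj$neighbourless_ids))),
            class = "spatial_weights")
}

## All interstate border segments, plus (optionally) outer-frame segments,
## grouped by state id. A segment belongs to a state's border when it
## separates that state from a different state (or, with the outer frame
## included, from the outside of the map).
state_border_segments <- function(geography, include_outer_frame = FALSE) {
  ids <- district_ids(geography)
  st <- state_of(geography)
  tol <- geo_tol(geography)
  edges <- lapply(geography$districts, function(d) ring_edges(d$ring))
  borders <- lapply(unique(st), function(s) NULL)
  names(borders) <- unique(st)
  n <- length(ids)
  # per-district, per-edge overlap intervals with any other district
  frame_cover <- if (include_outer_frame) {
    lapply(seq_len(n), function(i) vector("list", nrow(edges[[i]])))
  } else NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ei <- edges[[i]]; ej <- edges[[j]]
      for (a in seq_len(nrow(ei))) {
        for (b in seq_len(nrow(ej))) {
          ov <- colinear_overlap(ei[a, ], ej[b, ], tol)
          if (is.null(ov)) next
          if (include_outer_frame)
            frame_cover[[i]][[a]] <- rbind(frame_cover[[i]][[a]], ov)
          if (j > i && st[i] != st[j]) {
            p0 <- seg_point_at(ei[a, ], ov[1])
            p1 <- seg_point_at(ei[a, ], ov[2])
            seg <- c(p0, p1)
            borders[[st[i]]] <- rbind(borders[[st[i]]], seg)
            borders[[st[j]]] <- rbind(borders[[st[j]]], seg)
          }
        }
      }
    }
  }
  if (include_outer_frame) {
    for (i in seq_len(n)) {
      ei <- edges[[i]]
      elen <- sqrt((ei[, 3] - ei[, 1])^2 + (ei[, 4] - ei[, 2])^2)
      for (a in seq_len(nrow(ei))) {
        iv <- frame_cover[[i]][[a]]
        free <- interval_complement(iv)
        for (k in seq_len(nrow(free))) {
          if ((free[k, 2] - free[k, 1]) * elen[a] <= tol) next
          p0 <- seg_point_at(ei[a, ], free[k, 1])
          p1 <- seg_point_at(ei[a, ], free[k, 2])
          borders[[st[i]]] <- rbind(borders[[st[i]]], c(p0, p1))
        }
      }
    }
  }
  borders
}

## complement of a union of [lo, hi] intervals within [0, 1]
interval_complement <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(c(0, 1), 1))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[k, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], iv[k, 2])
    } else merged <- rbind(merged, iv[k, ])
  }
  out <- NULL
  prev <- 0
  for (k in seq_len(nrow(merged))) {
    if (merged[k, 1] > prev) out <- rbind(out, c(prev, merged[k, 1]))
    prev <- max(prev, merged[k, 2])
  }
  if (prev < 1) out <- rbind(out, c(prev, 1))
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

#' Border proximity factor (BPF)
#'
#' For each district, the mean Euclidean distance from the district to its
#' own state's border. By default the distance is averaged over points
#' sampled uniformly by arc length along the district boundary
#' (`method = "boundary"`); `method = "centroid"` uses the polygon centroid
#' instead. A state's border is the set of segments separating it from other
#' states; the outer frame of the study area is excluded unless
#' `include_outer_frame = TRUE`, so that districts far from any interstate
#' border get a large BPF even when they touch the map edge.
#'
#' @param geography a `district_geography` object; every district must carry
#'   a `state_id`.
#' @param n_boundary_samples number of boundary sample points per district.
#' @param method `"boundary"` (mean over boundary samples) or `"centroid"`.
#' @param include_outer_frame logical; count the study-area outline as part
#'   of each state's border.
#' @return data.frame with columns `district_id`, `bpf` (map units).
#' @export
compute_bpf <- function(geography, n_boundary_samples = 256,
                        method = c("boundary", "centroid"),
                        include_outer_frame = FALSE) {
  stopifnot(inherits(geography, "district_geography"))
  method <- match.arg(method)
  borders <- state_border_segments(geography, include_outer_frame)
  st <- state_of(geography)
  empty <- names(borders)[vapply(borders, is.null, TRUE)]
  if (length(empty) > 0)
    stop_config(paste0(
      "state(s) %s have no border segments (single-state map with the outer ",
      "frame excluded); set include_outer_frame = TRUE"),
      paste(empty, collapse = ", "))
  bpf <- vapply(seq_along(geography$districts), function(i) {
    d <- geography$districts[[i]]
    segs <- borders[[st[i]]]
    pts <- if (method == "boundary") {
      boundary_sample(d$ring, n_boundary_samples)
    } else {
      matrix(polygon_centroid(d$ring), 1)
    }
    mean(min_dist_to_segments(pts, segs))
  }, 0)
  data.frame(district_id = district_ids(geography), bpf = bpf,
             stringsAsFactors = FALSE)
}
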