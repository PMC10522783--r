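test_that("queen weights match hand-derived adjacency on small grids", {
  # 2x2 grid: complete queen graph, every weight 1/3
  g <- grid_map(2, 2)
  w <- queen_weights(g)
  expect_length(w$neighbourless_ids, 0)
  for (id in w$ids) {
    expect_length(w$neighbours[[id]], 3)
    expect_equal(w$weights[[id]], rep(1 / 3, 3))
  }

  # 1x3 strip: path graph
  g3 <- grid_map(3, 1)
  w3 <- queen_weights(g3)
  expect_setequal(w3$neighbours[["G02"]], c("G01", "G03"))
  expect_equal(w3$weights[["G02"]], c(0.5, 0.5))
  expect_equal(w3$neighbours[["G01"]], "G02")
  expect_equal(w3$weights[["G01"]], 1)
  expect_equal(w3$weights[["G03"]], 1)

  # adjacency is symmetric; row sums of standardized weights are 1
  gg <- generate_geography(3, 5, seed = 9)
  ww <- queen_weights(gg)
  for (id in ww$ids) {
    for (nb in ww$neighbours[[id]])
      expect_true(id %in% ww$neighbours[[nb]])
    if (!(id %in% ww$neighbourless_ids))
      expect_equal(sum(ww$weights[[id]]), 1)
  }
})

test_that("a detached island is neighbourless with zero weights", {
  isl <- district_geography(c(
    grid_map(2, 2)$districts,
    list(list(district_id = "ISL", state_id = "S1",
              ring = rbind(c(10, 10), c(11, 10), c(11, 11), c(10, 11))))))
  w <- queen_weights(isl)
  expect_equal(w$neighbourless_ids, "ISL")
  expect_length(w$weights[["ISL"]], 0)
})

test_that("duplicate ids and self-intersecting polygons are rejected", {
  d <- grid_map(2, 2)$districts
  d[[2]]$district_id <- d[[1]]$district_id
  expect_error(district_geography(d), "duplicate")
  bowtie <- list(list(district_id = "B", state_id = "S1",
                      ring = rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))))
  expect_error(district_geography(bowtie), "self-intersecting")
})

test_that("BPF matches exact geometry on constructed maps", {
  # a district whose entire boundary is its state's border
  g12 <- grid_map(2, 1, state_fun = function(ix, iy) c("A", "B")[ix])
  bpf <- compute_bpf(g12, include_outer_frame = TRUE)
  expect_equal(bpf$bpf, c(0, 0), tolerance = 1e-9)

  # with the outer frame excluded, the shared edge is the only border:
  # mean distance of a unit square boundary to its own left/right edge
  bpf2 <- compute_bpf(g12, n_boundary_samples = 4000)
  expect_equal(bpf2$bpf, c(0.5, 0.5), tolerance = 1e-3)

  # unit square centred in a 3x3 same-state block: every boundary point of
  # the inner square is at distance exactly 1 from the state outline
  g33 <- grid_map(3, 3)
  bpf3 <- compute_bpf(g33, include_outer_frame = TRUE)
  expect_equal(bpf3$bpf[bpf3$district_id == "G05"], 1, tolerance = 1e-9)

  # single-state map without the outer frame has no state border
  expect_error(compute_bpf(g33), "include_outer_frame")

  # centroid variant: centre of an end cell of a 1x3 two-state strip is
  # 1.5 units from the internal border at x = 1
  g13 <- grid_map(3, 1, state_fun = function(ix, iy) if (ix == 1) "A" else "B")
  bpfc <- compute_bpf(g13, method = "centroid")
  expect_equal(bpfc$bpf[bpfc$district_id == "G03"], 1.5, tolerance = 1e-9)
})

test_that("BPF agrees with a dense-discretization distance oracle", {
  # 1x3 strip split 1|2 between two states; internal border is x=1, y in [0,1]
  g13 <- grid_map(3, 1, state_fun = function(ix, iy) if (ix == 1) "A" else "B")
  bpf <- compute_bpf(g13, n_boundary_samples = 2048)

  # oracle: dense points on the border, dense points on the middle
  # district's boundary, brute-force nearest distances
  border_pts <- cbind(1, seq(0, 1, length.out = 10000))
  ring <- g13$districts[["G02"]]$ring
  bd <- saeipv:::boundary_sample(ring, 20000)
  d <- vapply(seq_len(nrow(bd)), function(i) {
    sqrt(min((bd[i, 1] - border_pts[, 1])^2 + (bd[i, 2] - border_pts[, 2])^2))
  }, 0)
  oracle <- mean(d)
  got <- bpf$bpf[bpf$district_id == "G02"]
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("BPF is translation invariant and scale equivariant; weights unchanged", {
  g <- generate_geography(2, 3, seed = 13)
  transform_geo <- function(geo, f) {
    district_geography(lapply(geo$districts, function(d) {
      d$ring <- t(apply(d$ring, 1, f)); d
    }))
  }
  b0 <- compute_bpf(g, n_boundary_samples = 64)
  w0 <- queen_weights(g)

  g_t <- transform_geo(g, function(p) p + c(13.7, -4.2))
  expect_equal(compute_bpf(g_t, n_boundary_samples = 64)$bpf, b0$bpf,
               tolerance = 1e-9)
  expect_equal(queen_weights(g_t)$neighbours, w0$neighbours)

  g_s <- transform_geo(g, function(p) p * 2.5)
  expect_equal(compute_bpf(g_s, n_boundary_samples = 64)$bpf, 2.5 * b0$bpf,
               tolerance = 1e-9)
  expect_equal(queen_weights(g_s)$weights, w0$weights)
})

test_that("geography and weights survive GeoJSON / JSON round trips", {
  g <- generate_geography(2, 3, seed = 21)
  f <- tempfile(fileext = ".geojson")
  write_geojson(g, f)
  g2 <- read_geojson(f)
  expect_equal(saeipv:::district_ids(g2), saeipv:::district_ids(g))
  expect_equal(g2$districts[["D001"]]$ring, g$districts[["D001"]]$ring)
  expect_equal(saeipv:::state_of(g2), saeipv:::state_of(g))

  w <- queen_weights(g)
  fw <- tempfile(fileext = ".json")
  write_weights(w, fw)
  w2 <- read_weights(fw)
  expect_equal(w2$neighbours, w$neighbours)
  expect_equal(w2$weights, w$weights)
  expect_equal(w2$neighbourless_ids, w$neighbourless_ids)
})
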