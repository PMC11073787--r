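# Mesh construction, validation, barycentric tiling, ray intersection and
# containment.

test_that("boxes are closed meshes with the analytic area and volume", {
  m <- make_box(c(0, 0, 0), c(1, 1, 1))
  expect_equal(nrow(m$triangles), 12L)
  v <- validate_mesh(m)
  expect_true(v$valid)
  mm <- mesh_measures(m)
  expect_equal(mm$area, 6)
  expect_equal(mm$volume, 1)
  # the membrane-model box: one face of area 0.47^2 = 0.2209
  m2 <- make_box(c(0, 0, 0), c(0.47, 0.47, 5))
  a <- triangle_areas(m2)
  expect_equal(a[1] + a[2], 0.2209)
  expect_equal(mesh_measures(m2)$volume, 0.47 * 0.47 * 5)
  expect_error(make_box(c(0, 0, 0), c(1, 0, 1)), "positive")
})

test_that("mesh diagnostics catch open edges, winding and degeneracy", {
  m <- make_box()
  holed <- m; holed$triangles <- m$triangles[-1, ]
  d <- validate_mesh(holed)
  expect_false(d$valid)
  expect_equal(nrow(d$open_edges), 3L)
  flipped <- m; flipped$triangles[2, ] <- rev(flipped$triangles[2, ])
  d2 <- validate_mesh(flipped)
  expect_false(d2$valid)
  expect_gt(nrow(d2$inconsistent_edges), 0L)
  degen <- m
  degen$vertices <- rbind(degen$vertices, degen$vertices[1, ] + 1e-13)
  degen$triangles <- rbind(degen$triangles, c(1L, 2L, 9L))
  expect_true(length(validate_mesh(degen)$degenerate_triangles) > 0L)
})

test_that("tiling follows n = ceil(sqrt(A sigma)) with density >= sigma", {
  # tiny triangle: A*sigma <= 1 -> a single tile
  tri <- structure(list(vertices = rbind(c(0, 0, 0), c(0.1, 0, 0),
                                         c(0, 0.1, 0)),
                        triangles = rbind(c(1L, 2L, 3L))), class = "mc_mesh")
  g <- tile_surface(tri, 10)
  expect_equal(g$n, 1L)
  expect_equal(g$n_tiles, 1L)
  # the 0.47 x 0.47 face at 40000 tiles/um^2: n = 67, 8978 tiles total
  face <- make_box(c(0, 0, 0), c(0.47, 0.47, 5))
  gf <- tile_surface(structure(list(
    vertices = face$vertices, triangles = face$triangles[1:2, ]),
    class = "mc_mesh"), 40000)
  expect_equal(gf$n, c(67L, 67L))
  expect_equal(gf$n_tiles, 8978L)
  expect_equal(gf$realized_density, 8978 / 0.2209)
  expect_gte(gf$realized_density, 40000)
  # per-triangle tile areas sum to the triangle area
  areas <- triangle_areas(face)[1:2]
  expect_equal(gf$tile_area * 67^2, areas, tolerance = 1e-9)
  # deterministic
  gf2 <- tile_surface(structure(list(
    vertices = face$vertices, triangles = face$triangles[1:2, ]),
    class = "mc_mesh"), 40000)
  expect_identical(gf[c("n", "offset", "n_tiles")],
                   gf2[c("n", "offset", "n_tiles")])
})

test_that("tile indexing is a bijection consistent with tile centers", {
  n <- 7L
  seen <- integer()
  for (k in 0:(n^2 - 1L)) {
    w <- colMeans(mcreact:::tile_corners_bary(n, k))
    k2 <- mcreact:::tile_index_bary(n, w[2], w[3])
    seen <- c(seen, k2)
  }
  expect_equal(sort(seen), 0:(n^2 - 1L))
})

test_that("ray-mesh hits are ordered, sided and watertight", {
  m <- make_box(c(0, 0, 0), c(1, 1, 1))
  # fully inside: no hits
  expect_equal(nrow(ray_mesh_intersections(c(0, 0, 0), c(0.2, 0.1, 0), m)), 0L)
  # axis-aligned crossing of the +x face at the analytic fraction
  h <- ray_mesh_intersections(c(0.1, 0, 0), c(1, 0, 0), m)
  expect_equal(nrow(h), 1L)
  expect_equal(h$t, 0.4)
  expect_equal(h$side, -1L)  # struck from inside (back face)
  # full crossing: two hits sorted by distance
  h2 <- ray_mesh_intersections(c(-1, 0.05, 0.05), c(2, 0, 0), m)
  expect_equal(nrow(h2), 2L)
  expect_true(all(diff(h2$t) > 0))
  expect_equal(h2$side, c(1L, -1L))
  # edge graze: the segment passes exactly through a face diagonal shared
  # by two triangles; counted once
  h3 <- ray_mesh_intersections(c(0, 0, -1), c(0, 0, 2), m)
  expect_equal(nrow(h3) %% 2L, 0L)
  expect_equal(nrow(h3), 2L)
})

test_that("hit parity is consistent with endpoint containment", {
  set.seed(11)
  m <- make_box(c(0.1, -0.2, 0), c(1.3, 0.8, 1.1))
  for (i in 1:60) {
    a <- stats::runif(3, -1.2, 1.2)
    b <- stats::runif(3, -1.2, 1.2)
    hits <- ray_mesh_intersections(a, b - a, m)
    same_side <- point_containment(a, m) == point_containment(b, m)
    expect_identical(nrow(hits) %% 2L == 0L, same_side)
  }
})

test_that("containment reproduces the volume fraction by Monte Carlo", {
  m <- make_box(c(0, 0, 0), c(1, 1, 1))
  expect_true(point_containment(c(0, 0, 0), m))
  expect_false(point_containment(c(5, 5, 5), m))
  set.seed(3)
  n <- 20000L
  pts <- matrix(stats::runif(3 * n, -0.75, 0.75), ncol = 3)
  inside <- vapply(seq_len(n), function(i) point_containment(pts[i, ], m),
                   logical(1))
  p_expect <- 1 / 1.5^3
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(mean(inside) - p_expect), 3 * se)
})

test_that("OBJ files round-trip with named regions", {
  m <- make_box(c(0, 0, 0), c(1, 2, 3))
  attr(m, "regions") <- list(bottom = c(1L, 2L), top = c(3L, 4L))
  f <- tempfile(fileext = ".obj")
  write_obj(m, f)
  m2 <- read_obj(f)
  expect_equal(nrow(m2$triangles), 12L)
  expect_equal(mesh_measures(m2)$volume, 6, tolerance = 1e-9)
  regs <- attr(m2, "regions")
  expect_length(regs$bottom, 2L)
  # region triangles enclose the same geometry (groups may reorder faces)
  tri_key <- function(mm, ix) {
    sort(apply(mm$triangles[ix, , drop = FALSE], 1, function(t)
      paste(sort(round(as.vector(mm$vertices[t, ]), 9)), collapse = ",")))
  }
  expect_equal(tri_key(m2, regs$bottom), tri_key(m, 1:2))
  # faces with /vt/vn suffixes parse too
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1/1/1 2/2/2 3/3/3"), f)
  m3 <- read_obj(f)
  expect_equal(nrow(m3$triangles), 1L)
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 1 1 0", "f 1 2 3 4"), f)
  expect_error(read_obj(f), "triangles only")
})
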