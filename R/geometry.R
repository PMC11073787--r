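# Triangulated-mesh geometry: construction, validation, OBJ I/O, barycentric
# surface tiling, ray-mesh intersection and point containment. Lengths are in
# um; counter-clockwise winding defines the outward normal.

#' Construct an axis-aligned box mesh
#'
#' @param center numeric xyz center (um).
#' @param dimensions numeric xyz edge lengths (um).
#' @return an `mc_mesh`: list with `vertices` (n x 3) and `triangles`
#'   (m x 3, 1-based, counter-clockwise seen from outside), 12 triangles.
#' @export
make_box <- function(center = c(0, 0, 0), dimensions = c(1, 1, 1)) {
  if (any(dimensions <= 0)) stop("box dimensions must be positive")
  h <- dimensions / 2
  sgn <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  v <- sweep(sweep(sgn, 2L, h, `*`), 2L, center, `+`)
  # vertex order: (-,-,-),(+,-,-),(-,+,-),(+,+,-),(-,-,+),(+,-,+),(-,+,+),(+,+,+)
  tris <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z- (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  mesh <- structure(list(vertices = unname(as.matrix(v)),
                         triangles = tris), class = "mc_mesh")
  mesh
}

tri_vertices <- function(mesh, i) {
  mesh$vertices[mesh$triangles[i, ], , drop = FALSE]
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Triangle areas of a mesh
#' @param mesh an `mc_mesh`.
#' @return numeric vector of areas (um^2).
#' @export
triangle_areas <- function(mesh) {
  vapply(seq_len(nrow(mesh$triangles)), function(i) {
    v <- tri_vertices(mesh, i)
    0.5 * sqrt(sum(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])^2))
  }, 0)
}

#' Surface area and enclosed volume of a closed mesh
#' @param mesh an `mc_mesh`.
#' @return list with `area` (um^2) and `volume` (um^3, by the divergence
#'   theorem; positive for consistent outward winding).
#' @export
mesh_measures <- function(mesh) {
  vol <- sum(vapply(seq_len(nrow(mesh$triangles)), function(i) {
    v <- tri_vertices(mesh, i)
    sum(v[1, ] * cross3(v[2, ], v[3, ])) / 6
  }, 0))
  list(area = sum(triangle_areas(mesh)), volume = vol)
}

#' Validate a triangulated mesh
#'
#' Reports open edges (undirected edges used by a single triangle),
#' inconsistent winding (directed edges traversed twice in the same
#' direction) and degenerate triangles (area below `area_eps`). A valid
#' compartment mesh is a closed 2-manifold with consistent winding and no
#' degenerate triangles.
#'
#' @param mesh an `mc_mesh`.
#' @param area_eps degeneracy threshold in um^2 (default 1e-12).
#' @return list with `valid`, `open_edges` (k x 2 vertex indices),
#'   `inconsistent_edges` (k x 2) and `degenerate_triangles` (indices).
#' @export
validate_mesh <- function(mesh, area_eps = 1e-12) {
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3])
  to <- c(tr[, 2], tr[, 3], tr[, 1])
  dir_key <- paste(from, to)
  und_key <- paste(pmin(from, to), pmax(from, to))
  und_tab <- table(und_key)
  open <- names(und_tab)[und_tab == 1L]
  dir_tab <- table(dir_key)
  inconsistent <- names(dir_tab)[dir_tab > 1L]
  degen <- which(triangle_areas(mesh) < area_eps)
  parse_edges <- function(keys) {
    if (!length(keys)) return(matrix(integer(), 0L, 2L))
    do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  }
  out <- list(open_edges = parse_edges(open),
              inconsistent_edges = parse_edges(inconsistent),
              degenerate_triangles = degen)
  out$valid <- nrow(out$open_edges) == 0L &&
    nrow(out$inconsistent_edges) == 0L && length(degen) == 0L
  out
}

#' Read a Wavefront OBJ mesh (triangles only)
#'
#' Supports `v` and `f` records (1-based indices; `f` entries may carry
#' `/vt/vn` suffixes, which are ignored) and `g` group records, which define
#' named surface regions (triangle subsets). Normals are recomputed from
#' winding, never read.
#'
#' @param path OBJ file.
#' @return an `mc_mesh` with a `regions` attribute (named list of triangle
#'   index vectors) when groups are present.
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  verts <- list(); tris <- list(); regions <- list()
  group <- NA_character_
  for (ln in lines) {
    ln <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (f[1] == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(f[2:4])
    } else if (f[1] == "f") {
      ix <- as.integer(sub("/.*$", "", f[-1]))
      if (length(ix) != 3L)
        stop("OBJ face with ", length(ix), " vertices: triangles only")
      tris[[length(tris) + 1L]] <- ix
      if (!is.na(group))
        regions[[group]] <- c(regions[[group]], length(tris))
    } else if (f[1] == "g") {
      group <- if (length(f) > 1L) f[2] else NA_character_
    }
  }
  mesh <- structure(list(vertices = do.call(rbind, verts),
                         triangles = do.call(rbind, tris)),
                    class = "mc_mesh")
  if (length(regions)) attr(mesh, "regions") <- regions
  mesh
}

#' Write a mesh as Wavefront OBJ
#' @param mesh an `mc_mesh` (named regions from the `regions` attribute are
#'   written as `g` groups).
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  regions <- attr(mesh, "regions")
  if (is.null(regions)) {
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  } else {
    written <- logical(nrow(mesh$triangles))
    for (nm in names(regions)) {
      writeLines(paste("g", nm), con)
      ix <- regions[[nm]]
      writeLines(sprintf("f %d %d %d", mesh$triangles[ix, 1],
                         mesh$triangles[ix, 2], mesh$triangles[ix, 3]), con)
      written[ix] <- TRUE
    }
    if (any(!written)) {
      writeLines("g default", con)
      ix <- which(!written)
      writeLines(sprintf("f %d %d %d", mesh$triangles[ix, 1],
                         mesh$triangles[ix, 2], mesh$triangles[ix, 3]), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Barycentric surface grid

#' Tile a mesh with a barycentric surface grid
#'
#' Each triangle of area A is subdivided into n^2 congruent-area cells with
#' n = ceiling(sqrt(A * sigma)) strips, so the realized tile density is at
#' least the requested density sigma. At most one surface molecule can occupy
#' a tile; tiles are indexed strip-major within each triangle.
#'
#' @param mesh an `mc_mesh`.
#' @param sigma requested grid density in tiles/um^2.
#' @return an `mc_surface_grid`: list with `mesh`, `sigma`, per-triangle
#'   subdivision `n`, per-triangle `offset` into the flat tile index space,
#'   `n_tiles`, per-triangle `tile_area`, and `realized_density`.
#' @export
tile_surface <- function(mesh, sigma) {
  if (sigma <= 0) stop("grid density must be positive")
  areas <- triangle_areas(mesh)
  n <- pmax(1L, as.integer(ceiling(sqrt(areas * sigma) - 1e-9)))
  ntiles <- n^2
  offset <- c(0L, cumsum(ntiles))
  structure(list(mesh = mesh, sigma = sigma, n = n,
                 offset = offset[-length(offset)],
                 n_tiles = sum(ntiles), tile_area = areas / ntiles,
                 realized_density = sum(ntiles) / sum(areas)),
            class = "mc_surface_grid")
}

# barycentric corners (weights on triangle vertices V1,V2,V3) of tile k
# (0-based) of a triangle subdivided n-fold. Rows j (0-based, distance from
# the V1-V2 edge) hold 2(n-j)-1 tiles: upward tiles first by i, interleaved
# with downward tiles.
tile_corners_bary <- function(n, k) {
  j <- 0L
  while (k >= 2L * (n - j) - 1L) { k <- k - (2L * (n - j) - 1L); j <- j + 1L }
  i <- k %/% 2L
  up <- k %% 2L == 0L
  if (up) {
    b <- rbind(c(i, j), c(i + 1L, j), c(i, j + 1L))
  } else {
    b <- rbind(c(i + 1L, j), c(i + 1L, j + 1L), c(i, j + 1L))
  }
  cbind(1 - rowSums(b) / n, b[, 1] / n, b[, 2] / n)  # (w1, w2, w3)
}

# tile index (0-based) from barycentric weights (w1,w2,w3)
tile_index_bary <- function(n, w2, w3) {
  x <- n * w2; y <- n * w3
  i <- as.integer(min(max(floor(x), 0), n - 1L))
  j <- as.integer(min(max(floor(y), 0), n - 1L))
  down <- (x - i) + (y - j) > 1
  if (i + j > n - 1L || (down && i + j > n - 2L)) {
    # numeric spill outside the triangle: clamp to an upward diagonal cell
    down <- FALSE
    if (i + j > n - 1L) {
      s <- i + j - (n - 1L)
      i <- max(0L, i - s); j <- (n - 1L) - i
    }
  }
  offset_j <- j * (2L * n - j)
  as.integer(offset_j + 2L * i + if (down) 1L else 0L)
}

#' Center of a surface-grid tile
#' @param grid an `mc_surface_grid`.
#' @param tri triangle index (1-based).
#' @param tile tile index within the triangle (0-based).
#' @return xyz coordinates (um).
#' @export
tile_center <- function(grid, tri, tile) {
  w <- colMeans(tile_corners_bary(grid$n[tri], tile))
  v <- tri_vertices(grid$mesh, tri)
  as.numeric(w %*% v)
}

#' @export
print.mc_mesh <- function(x, ...) {
  mm <- mesh_measures(x)
  cat("<mc_mesh>", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles, area", signif(mm$area, 6), "um^2, volume",
      signif(mm$volume, 6), "um^3\n")
  invisible(x)
}

#' @export
print.mc_surface_grid <- function(x, ...) {
  cat("<mc_surface_grid>", x$n_tiles, "tiles, requested density", x$sigma,
      "/um^2, realized", signif(x$realized_density, 6), "/um^2\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Ray-mesh intersection and containment (C++ backed)

#' Intersections of a displacement segment with a mesh
#'
#' Hits are returned sorted by distance fraction along the displacement;
#' `side` is +1 when the segment strikes the front (outward-normal) face and
#' -1 for the back face. Edge/vertex grazings are counted once, for the
#' lowest-index triangle.
#'
#' @param origin,displacement numeric xyz (um).
#' @param mesh an `mc_mesh`.
#' @return data frame with columns `t` (fraction in [0,1]), `triangle`
#'   (1-based) and `side`.
#' @export
ray_mesh_intersections <- function(origin, displacement, mesh) {
  h <- cpp_ray_mesh_hits(as.numeric(origin), as.numeric(displacement),
                         mesh$vertices, mesh$triangles)
  data.frame(t = h[, 1], triangle = as.integer(h[, 2]),
             side = as.integer(h[, 3]))
}

#' Point containment in a closed mesh
#'
#' Crossing-parity test along a fixed ray direction; points on the surface
#' resolve to inside.
#'
#' @param p numeric xyz (um).
#' @param mesh a validated closed `mc_mesh`.
#' @return `TRUE` if inside.
#' @export
point_containment <- function(p, mesh) {
  cpp_point_in_mesh(as.numeric(p), mesh$vertices, mesh$triangles)
}
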