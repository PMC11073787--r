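# World assembly and the simulation loop. The world couples the R-side
# rule engine (graphs, canonical species, pathway expansion) to the compiled
# Monte Carlo core through two provider callbacks that expand reaction
# classes on demand (network-free direct evaluation). All randomness flows
# from a single seedable 64-bit stream owned by the world.

#' Simulation configuration
#'
#' @param dt time step in seconds (default 1e-6, the typical step for
#'   bimolecular interactions).
#' @param seed RNG seed for the world's single random stream.
#' @param grid_density surface grid density sigma in tiles/um^2 (default
#'   1e4). Sets surface volume exclusion and the volume-surface collision
#'   cross-section.
#' @param interaction_radius r_int in um. Default `1/sqrt(pi * grid_density)`
#'   which makes the volume collision cross-section pi*r_int^2 equal to the
#'   area of one surface tile.
#' @param cleanup_interval iterations between species/reaction cache
#'   cleanups (0 disables; default 10000).
#' @param count_stride record observables every this many iterations.
#' @param units unit system for rate constants in the model: `"mcell"`
#'   (volume bimolecular in M^-1 s^-1, surface-surface in um^2 N^-1 s^-1) or
#'   `"bng"` (all bimolecular in um^3 N^-1 s^-1).
#' @param vs_const,ss_const calibration constants of the volume-surface and
#'   surface-surface collision probability factors (see the methods
#'   vignette; defaults fixed by mass-action calibration against the
#'   ODE oracle).
#' @return list of class `mc_config`.
#' @export
simulation_config <- function(dt = 1e-6, seed = 1, grid_density = 1e4,
                              interaction_radius = 1 / sqrt(pi * grid_density),
                              cleanup_interval = 10000L, count_stride = 1L,
                              units = c("mcell", "bng"),
                              vs_const = 1, ss_const = 5.5) {
  stopifnot(dt > 0, interaction_radius > 0, grid_density > 0)
  structure(list(dt = dt, seed = seed, grid_density = grid_density,
                 rint = interaction_radius,
                 cleanup_interval = as.integer(cleanup_interval),
                 count_stride = as.integer(count_stride),
                 units = match.arg(units),
                 vs_const = vs_const, ss_const = ss_const),
            class = "mc_config")
}

#' Gaussian displacement sampler for Brownian motion
#'
#' Each axis is an independent Gaussian with variance 2*D*dt (D converted
#' from cm^2/s to um^2/s). Used for distribution-level checks; the engine
#' draws the same law from its own stream.
#'
#' @param D diffusion constant in cm^2/s.
#' @param dt time step in s.
#' @param n number of displacement vectors.
#' @param dim 2 or 3.
#' @return n x dim matrix of displacements in um.
#' @export
sample_displacement <- function(D, dt, n = 1L, dim = 3L) {
  stopifnot(D >= 0, dim %in% c(2L, 3L))
  sd <- sqrt(2 * D * 1e8 * dt)
  matrix(stats::rnorm(n * dim, 0, sd), n, dim)
}

#' Per-collision reaction probability, volume-volume
#'
#' p = k dt / (pi r_int^2 (lbar_A + lbar_B)) with lbar = sqrt(16 D dt / pi)
#' the mean diffusion step length. Calibrated so a well-mixed system
#' reproduces mass action; p > 1 means reactions are being missed and is
#' reported by the run summary.
#'
#' @param k bimolecular rate constant in um^3 N^-1 s^-1.
#' @param D_A,D_B diffusion constants (cm^2/s).
#' @param r_int interaction radius (um).
#' @param dt time step (s).
#' @return probability per collision test.
#' @export
reaction_probability_vv <- function(k, D_A, D_B, r_int, dt) {
  lbar <- function(D) sqrt(16 * D * 1e8 * dt / pi)
  k * dt / (pi * r_int^2 * (lbar(D_A) + lbar(D_B)))
}

#' Per-wall-hit reaction probability, volume-surface
#'
#' p = k dt / (c A_tile sqrt(D dt / pi)); the constant c (default 1) is
#' fixed by mass-action calibration against the ODE oracle and agrees with
#' the one-sided diffusive flux onto a tile, n A sqrt(D dt / pi) hits per
#' time step at number density n.
#'
#' @param k rate constant in um^3 N^-1 s^-1.
#' @param D_vol diffusion constant of the volume reactant (cm^2/s).
#' @param tile_area area of the struck tile (um^2).
#' @param dt time step (s).
#' @param vs_const calibration constant.
#' @return probability per wall-tile hit.
#' @export
reaction_probability_vs <- function(k, D_vol, tile_area, dt, vs_const = 1) {
  k * dt / (vs_const * tile_area * sqrt(D_vol * 1e8 * dt / pi))
}

## ---------------------------------------------------------------------------
## Geometry objects and releases

#' Define a geometry object
#'
#' @param mesh an `mc_mesh` (closed for compartment meshes).
#' @param name object name.
#' @param inside_compartment optional 3D compartment name that the mesh
#'   bounds.
#' @param surface_compartment optional 2D compartment name carried by the
#'   mesh surface.
#' @param regions named list of triangle index vectors (surface regions);
#'   defaults to the mesh's `regions` attribute.
#' @param region_edges_reflective character vector of region names whose
#'   boundary edges reflect 2D diffusion.
#' @return list of class `mc_geometry_object`.
#' @export
geometry_object <- function(mesh, name, inside_compartment = NA,
                            surface_compartment = NA, regions = NULL,
                            region_edges_reflective = character()) {
  structure(list(mesh = mesh, name = name,
                 inside = inside_compartment, surface = surface_compartment,
                 regions = regions %||% attr(mesh, "regions") %||% list(),
                 refl_regions = region_edges_reflective),
            class = "mc_geometry_object")
}

#' Define a release site
#'
#' @param species BNGL complex string (or `mc_complex`) of the species to
#'   release.
#' @param shape `"volume"` (uniform in a geometry object by rejection
#'   sampling), `"surface"` (uniform over vacant tiles of an object/region)
#'   or `"points"` (fixed coordinates).
#' @param count number of molecules (ignored when `density` given for
#'   surface releases).
#' @param density surface density in N/um^2; the released count is
#'   round(density * region area).
#' @param object,region target geometry object name and optional region
#'   name.
#' @param points n x 3 matrix of positions (um) for `shape = "points"`.
#' @param time release time in seconds (mapped to an iteration); a vector
#'   together with a vector `count` defines a timed influx schedule.
#' @return list of class `mc_release_site`.
#' @export
release_site <- function(species, shape = c("volume", "surface", "points"),
                         count = NULL, density = NULL, object = NULL,
                         region = NULL, points = NULL, time = 0) {
  shape <- match.arg(shape)
  if (!is.null(count) && any(count < 0)) stop("release count must be >= 0")
  if (!is.null(density) && density < 0) stop("release density must be >= 0")
  structure(list(species = species, shape = shape, count = count,
                 density = density, object = object, region = region,
                 points = points, time = time),
            class = "mc_release_site")
}

## ---------------------------------------------------------------------------
## World construction

prepare_geometry <- function(objects, compartments, comp_ids, sigma) {
  if (!length(objects)) return(NULL)
  verts <- NULL; tris <- NULL
  tri_obj <- integer(); tri_region <- integer()
  region_names <- character(); region_refl <- logical()
  obj_comp_in <- integer(length(objects))
  obj_comp_out <- integer(length(objects))
  obj_surf <- integer(length(objects))
  obj_names <- vapply(objects, `[[`, "", "name")
  for (oi in seq_along(objects)) {
    ob <- objects[[oi]]
    voff <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, ob$mesh$vertices)
    t0 <- if (is.null(tris)) 0L else nrow(tris)
    tris <- rbind(tris, ob$mesh$triangles + voff)
    nt <- nrow(ob$mesh$triangles)
    tri_obj <- c(tri_obj, rep(oi, nt))
    reg <- rep(0L, nt)
    for (rn in names(ob$regions)) {
      region_names <- c(region_names, paste0(ob$name, ":", rn))
      region_refl <- c(region_refl, rn %in% ob$refl_regions)
      reg[ob$regions[[rn]]] <- length(region_names)
    }
    tri_region <- c(tri_region, reg)
    cin <- if (!is.na(ob$inside)) comp_ids[[ob$inside]] else 0L
    obj_comp_in[oi] <- cin %||% 0L
    obj_surf[oi] <- (if (!is.na(ob$surface)) comp_ids[[ob$surface]] else 0L) %||% 0L
    cout <- 0L
    if (!is.na(ob$surface)) {
      par <- compartments[[ob$surface]]$parent
      if (!is.null(par) && !is.na(par)) cout <- comp_ids[[par]] %||% 0L
    } else if (!is.na(ob$inside)) {
      # parent chain: 3D -> 2D -> 3D
      par2 <- compartments[[ob$inside]]$parent
      if (!is.null(par2) && !is.na(par2)) {
        par3 <- compartments[[par2]]$parent
        if (!is.null(par3) && !is.na(par3)) cout <- comp_ids[[par3]] %||% 0L
      }
    }
    obj_comp_out[oi] <- cout
  }
  # per-object edge adjacency
  nt <- nrow(tris)
  tri_nbr <- matrix(0L, nt, 3L)
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  emap <- new.env(parent = emptyenv())
  for (i in seq_len(nt)) {
    for (e in 1:3) {
      a <- tris[i, e]; b <- tris[i, e %% 3 + 1]
      k <- ekey(a, b)
      lst <- emap[[k]] %||% integer()
      emap[[k]] <- c(lst, i)
    }
  }
  for (i in seq_len(nt)) {
    for (e in 1:3) {
      a <- tris[i, e]; b <- tris[i, e %% 3 + 1]
      lst <- emap[[ekey(a, b)]]
      other <- setdiff(lst, i)
      if (length(other) == 1L && tri_obj[other] == tri_obj[i])
        tri_nbr[i, e] <- other
    }
  }
  # tiling
  mesh_all <- structure(list(vertices = verts, triangles = tris),
                        class = "mc_mesh")
  areas <- triangle_areas(mesh_all)
  n <- pmax(1L, as.integer(ceiling(sqrt(areas * sigma) - 1e-9)))
  off <- c(0L, cumsum(n^2))
  list(verts = verts, tris = tris, tri_obj = tri_obj,
       tri_region = tri_region, tri_nbr = tri_nbr,
       tri_n = n, tri_off = off[-length(off)], n_tiles = sum(n^2),
       occup = integer(sum(n^2)),
       obj_comp_in = obj_comp_in, obj_comp_out = obj_comp_out,
       obj_surf_comp = obj_surf,
       region_edge_reflective = as.integer(region_refl),
       region_names = region_names, obj_names = obj_names,
       surf_class = matrix(0L, 0L, 4L), mesh = mesh_all)
}

internal_rate <- function(rate, context, units) {
  if (context == "unimol") return(rate)
  if (units == "mcell") {
    if (context == "vol_bimol")
      convert_rate_units(rate, "vol_bimol", "mcell", "bng")  # -> um^3/N/s
    else rate                                                # um^2/N/s already
  } else {
    if (context == "vol_bimol") rate                         # um^3/N/s
    else rate / 0.01                                         # um^3 -> um^2
  }
}

#' Build a simulation world from a model bundle
#'
#' Resolves compartment classes against the geometry, converts rate
#' constants to internal units, registers the seed species in the species
#' cache, compiles observables, and prepares the initial releases.
#'
#' @param bundle an `mc_model_bundle` (see [model_bundle()] and
#'   [load_bngl_into_model()]).
#' @return an `mc_world` environment.
#' @export
build_world <- function(bundle) {
  w <- new.env(parent = emptyenv())
  class(w) <- "mc_world"
  w$bundle <- bundle
  w$config <- bundle$config
  m <- bundle$bngl
  w$types <- m$molecule_types
  w$compartments <- m$compartments
  w$comp_ids <- stats::setNames(seq_along(m$compartments),
                                names(m$compartments))
  w$cache <- species_cache()
  w$geom <- prepare_geometry(bundle$geometry, m$compartments, w$comp_ids,
                             bundle$config$grid_density)

  # resolve @IN/@OUT against each membrane-carrying object
  rules <- list()
  for (r in m$reaction_rules) {
    tags <- c(vapply(r$reactants, function(g) g$compartment, character(1)),
              vapply(r$products, function(g) g$compartment, character(1)))
    if (any(tags %in% c("IN", "OUT"), na.rm = TRUE)) {
      membranes <- names(m$compartments)[vapply(m$compartments,
        function(cp) cp$dim == 2L, logical(1))]
      for (mem in membranes) {
        rr <- try(resolve_compartment_classes(r, mem, m$compartments,
                                              w$types), silent = TRUE)
        if (!inherits(rr, "try-error")) {
          rr$name <- if (length(membranes) > 1L)
            paste0(r$name, "@", mem) else r$name
          rules[[length(rules) + 1L]] <- rr
        }
      }
    } else {
      rules[[length(rules) + 1L]] <- r
    }
  }
  # convert rates to internal units
  w$rules <- lapply(rules, function(r) {
    ctx <- rule_context(r, w$types)
    r$context <- ctx
    r$rate_model <- r$rate
    r$rate <- internal_rate(r$rate, ctx, bundle$config$units)
    r
  })
  w$rule_names <- vapply(w$rules, `[[`, "", "name")

  # observables
  w$obs <- bundle$observables
  w$obs_names <- vapply(w$obs, `[[`, "", "name")
  w$obs_scope <- vapply(w$obs, function(o) {
    sc <- o$scope %||% NA_character_
    if (is.na(sc)) 0L else (w$comp_ids[[sc]] %||% 0L)
  }, 0L)
  w$obs_rule <- vapply(w$obs, function(o) {
    rn <- o$count_rule %||% NA_character_
    if (is.na(rn)) 0L else match(rn, w$rule_names, nomatch = 0L)
  }, 0L)

  # surface classes: rows (species_type, object, region, behavior)
  if (!is.null(w$geom) && length(bundle$surface_classes)) {
    w$surface_class_spec <- bundle$surface_classes
  } else {
    w$surface_class_spec <- list()
  }

  # molecule state
  w$vol <- list(id = integer(), sp = integer(), comp = integer(),
                born = integer(), x = numeric(), y = numeric(), z = numeric(),
                tun = numeric())
  w$surf <- list(id = integer(), sp = integer(), tri = integer(),
                 tile = integer(), born = integer(), tun = numeric())
  w$next_id <- 1L
  w$iter <- 0L
  w$time <- 0
  w$rng_state <- as.raw(rep(0L, 32L))
  w$fired <- numeric(length(w$rules))
  w$counts <- NULL
  w$warnings <- character()
  w$pstats <- NULL
  w$cpp_known <- 0L
  w$callbacks <- bundle$callbacks %||% list()
  w$hybrid <- bundle$hybrid

  # seed species + bundle releases -> engine release list
  w$pending_releases <- list()
  for (s in m$seed_species) {
    if (s$count == 0L) next
    sp_id <- register_species(w$cache, s$graph, w$types)
    cp <- s$graph$compartment
    dim <- w$cache$info[[sp_id]]$dim
    if (is.null(w$geom))
      stop("seed species require geometry (map compartments to meshes)")
    if (dim == 3L) {
      oi <- which(vapply(bundle$geometry, function(o)
        identical(o$inside, cp), logical(1)))
      if (!length(oi)) stop("no geometry object for compartment '", cp, "'")
      w$pending_releases[[length(w$pending_releases) + 1L]] <- list(
        iter = 0L, kind = 0L, sp = sp_id, count = s$count, density = 0,
        obj = oi[1L], region = 0L, comp = w$comp_ids[[cp]] %||% 0L,
        pts = matrix(0, 0, 3))
    } else {
      oi <- which(vapply(bundle$geometry, function(o)
        identical(o$surface, cp), logical(1)))
      if (!length(oi)) stop("no geometry object for membrane '", cp, "'")
      w$pending_releases[[length(w$pending_releases) + 1L]] <- list(
        iter = 0L, kind = 1L, sp = sp_id, count = s$count, density = 0,
        obj = oi[1L], region = 0L, comp = 0L, pts = matrix(0, 0, 3))
    }
  }
  for (rs in bundle$releases) queue_release(w, rs)
  w
}

queue_release <- function(w, rs) {
  g <- if (inherits(rs$species, "mc_complex")) rs$species
       else parse_complex(rs$species, w$types)
  sp_id <- register_species(w$cache, g, w$types)
  obj <- if (!is.null(rs$object))
    match(rs$object, vapply(w$bundle$geometry, `[[`, "", "name")) else NA
  region <- 0L
  if (!is.null(rs$region) && !is.null(w$geom)) {
    region <- match(paste0(rs$object, ":", rs$region), w$geom$region_names,
                    nomatch = 0L)
    if (region == 0L) stop("unknown surface region '", rs$region, "'")
  }
  times <- rs$time
  counts <- rs$count %||% rep(0L, length(times))
  if (length(counts) == 1L) counts <- rep(counts, length(times))
  for (k in seq_along(times)) {
    kind <- switch(rs$shape, points = 2L,
                   volume = 0L,
                   surface = if (!is.null(rs$density)) 3L else 1L)
    cp <- g$compartment
    w$pending_releases[[length(w$pending_releases) + 1L]] <- list(
      iter = as.integer(round(times[k] / w$config$dt)), kind = kind,
      sp = sp_id, count = as.integer(counts[k] %||% 0L),
      density = rs$density %||% 0,
      obj = if (is.na(obj)) 0L else obj, region = region,
      comp = if (!is.na(cp) && !is.null(w$comp_ids[[cp]]))
        w$comp_ids[[cp]] else 0L,
      pts = if (is.null(rs$points)) matrix(0, 0, 3) else rs$points)
  }
  invisible(w)
}

## ---------------------------------------------------------------------------
## Providers: R-side pathway expansion serving the compiled core

obs_rows_for <- function(w, ids) {
  if (!length(w$obs)) return(matrix(0, length(ids), 0L))
  out <- matrix(0, length(ids), length(w$obs))
  for (k in seq_along(ids)) {
    g <- species_graph(w$cache, ids[k])
    for (o in seq_along(w$obs)) {
      ob <- w$obs[[o]]
      if (!is.na(ob$count_rule %||% NA_character_)) next
      val <- 0
      for (p in ob$patterns) {
        ne <- length(match_pattern(p, g))
        if (ob$kind == "Species") { if (ne > 0) { val <- 1; break } }
        else val <- val + ne
      }
      out[k, o] <- val
    }
  }
  out
}

new_species_payload <- function(w) {
  ids <- seq_len(w$cache$next_id)
  ids <- ids[ids > w$cpp_known]
  if (!length(ids)) return(NULL)
  info <- lapply(ids, function(i) w$cache$info[[i]])
  D <- vapply(info, function(x) if (is.na(x$D)) 0 else x$D, 0)
  dims <- vapply(info, `[[`, 0L, "dim")
  comp <- vapply(info, function(x) {
    cp <- x$compartment
    if (is.na(cp) || is.null(w$comp_ids[[cp]])) 0L else w$comp_ids[[cp]]
  }, 0L)
  obs <- obs_rows_for(w, ids)
  w$cpp_known <- max(ids)
  list(D = D, dim = dims, comp = comp, obs = obs)
}

pathway_payload <- function(w, cls) {
  pw <- cls$pathways
  hyb_rule <- if (!is.null(w$hybrid)) w$hybrid$coupled_rule else ""
  list(rate = vapply(pw, `[[`, 0, "rate"),
       context = vapply(pw, function(p)
         switch(p$context, unimol = 0L, vol_bimol = 1L, surf_bimol = 2L), 0L),
       rule = vapply(pw, function(p)
         match(p$rule, w$rule_names, nomatch = 0L), 0L),
       prods = lapply(pw, function(p) as.integer(p$products)),
       dyncoef = vapply(pw, function(p)
         if (identical(p$rule, hyb_rule)) w$hybrid$coupled_coef else 0, 0))
}

make_providers <- function(w) {
  list(
    bimol = function(a, b) {
      cls <- lookup_or_expand(w$cache, c(a, b), w$rules, w$types)
      pw <- pathway_payload(w, cls)
      ns <- new_species_payload(w)
      if (is.null(ns)) list(pw = pw) else list(pw = pw, new_species = ns)
    },
    unimol = function(a) {
      cls <- lookup_or_expand(w$cache, a, w$rules, w$types)
      pw <- pathway_payload(w, cls)
      ns <- new_species_payload(w)
      if (is.null(ns)) list(pw = pw) else list(pw = pw, new_species = ns)
    })
}

## ---------------------------------------------------------------------------
## Running

build_engine_state <- function(w, n) {
  ids <- seq_len(w$cache$next_id)
  if (w$cpp_known < length(ids)) {
    # make sure the core starts with the full current species table
    ns <- new_species_payload(w)
    if (!is.null(ns)) {
      w$species_tab <- NULL
    }
  }
  info <- lapply(ids, function(i) w$cache$info[[i]])
  D <- vapply(info, function(x) if (is.na(x$D)) 0 else x$D, 0)
  dims <- vapply(info, `[[`, 0L, "dim")
  comp <- vapply(info, function(x) {
    cp <- x$compartment
    if (is.na(cp) || is.null(w$comp_ids[[cp]])) 0L else w$comp_ids[[cp]]
  }, 0L)
  obsmat <- obs_rows_for(w, ids)
  w$cpp_known <- length(ids)

  geom <- w$geom
  if (!is.null(geom)) {
    geom$surf_class <- surface_class_rows(w)
  }
  hybrid <- NULL
  if (!is.null(w$hybrid)) {
    h <- w$hybrid
    sp_of <- function(x) vapply(x, function(s)
      register_species(w$cache, parse_complex(s, w$types), w$types), 0L)
    hybrid <- list(value = h$value,
                   decay = h$decay,
                   prod_sp = if (length(h$prod)) sp_of(names(h$prod)) else integer(),
                   prod_coef = as.numeric(h$prod),
                   cons_sp = if (length(h$cons)) sp_of(names(h$cons)) else integer(),
                   cons_coef = as.numeric(h$cons),
                   gain_rules = vapply(h$gain_rules, function(rn)
                     match(rn, w$rule_names, nomatch = 0L), 0L),
                   coupled_rule = match(h$coupled_rule, w$rule_names,
                                        nomatch = 0L),
                   coupled_coef = h$coupled_coef)
  }
  list(cfg = list(dt = w$config$dt, rint = w$config$rint, n_iter = as.integer(n),
                  iter0 = w$iter, time0 = w$time,
                  count_stride = w$config$count_stride,
                  cleanup_interval = w$config$cleanup_interval,
                  vs_const = w$config$vs_const, ss_const = w$config$ss_const,
                  rng_state = w$rng_state, seed = as.double(w$config$seed)),
       species = list(D = D, dim = dims, comp = comp),
       obsmat = obsmat,
       obs_scope = as.integer(w$obs_scope),
       obs_rule = as.integer(w$obs_rule),
       n_rules = length(w$rules),
       fired = w$fired,
       vol = w$vol, surf = w$surf, next_id = w$next_id,
       geom = geom,
       releases = w$pending_releases,
       hybrid = hybrid)
}

surface_class_rows <- function(w) {
  spec <- w$surface_class_spec
  if (!length(spec)) return(matrix(0L, 0L, 4L))
  rows <- NULL
  obj_names <- w$geom$obj_names
  behavior_code <- c(reflective = 0L, transparent = 1L, absorptive = 2L)
  for (sc in spec) {
    oi <- match(sc$object, obj_names)
    if (is.na(oi)) stop("unknown geometry object '", sc$object, "'")
    region <- 0L
    if (!is.null(sc$region)) {
      region <- match(paste0(sc$object, ":", sc$region), w$geom$region_names,
                      nomatch = 0L)
    }
    beh <- behavior_code[[sc$behavior]]
    sp_ids <- 0L
    if (!is.null(sc$species)) {
      # apply to every registered species containing the named molecule type
      ids <- seq_len(w$cache$next_id)
      sp_ids <- ids[vapply(ids, function(i) {
        g <- species_graph(w$cache, i)
        !is.null(g) && sc$species %in% g$mol_type
      }, logical(1))]
      if (!length(sp_ids)) next
    }
    for (s in sp_ids) rows <- rbind(rows, c(s, oi, region, beh))
  }
  if (is.null(rows)) matrix(0L, 0L, 4L) else {
    storage.mode(rows) <- "integer"
    rows
  }
}

#' Advance a world by n iterations
#'
#' Per iteration the events run in the fixed order release -> diffuse/react
#' -> hybrid update -> count. Identical (model, seed, config) produce
#' bit-identical trajectories; the cache cleanup interval has no effect on
#' the trajectory.
#'
#' @param world an `mc_world` from [build_world()].
#' @param n number of iterations.
#' @return the world, invisibly; counts accumulate in `world$counts`.
#' @export
run_iterations <- function(world, n) {
  n <- as.integer(n)
  if (n == 0L) return(invisible(world))
  st <- build_engine_state(world, n)
  prov <- make_providers(world)
  cbs <- list(
    rxn = lapply(Filter(function(cb) cb$kind == "reaction", world$callbacks),
                 function(cb) list(rule = match(cb$trigger, world$rule_names,
                                                nomatch = 0L),
                                   fn = cb$fn, ctx = cb$context)),
    wall = lapply(Filter(function(cb) cb$kind == "wall_hit", world$callbacks),
                  function(cb) {
                    sp <- 0L
                    if (!is.null(cb$species)) {
                      g <- parse_complex(cb$species, world$types)
                      sp <- register_species(world$cache, g, world$types)
                    }
                    obj <- 0L
                    if (!is.null(cb$object))
                      obj <- match(cb$object, world$geom$obj_names,
                                   nomatch = 0L)
                    list(sp = sp, obj = obj, fn = cb$fn, ctx = cb$context)
                  }))
  res <- cpp_run_engine(st, prov, cbs)
  world$vol <- res$vol
  world$surf <- res$surf
  if (!is.null(world$geom)) world$geom$occup <- res$occup
  world$rng_state <- res$rng_state
  world$next_id <- res$next_id
  world$fired <- res$fired
  world$pstats <- res$pstats
  world$time <- res$time
  world$iter <- res$iter
  world$warnings <- c(world$warnings, res$warnings)
  # molecule counts back into the cache (cleanup bookkeeping)
  for (i in seq_along(res$sp_count)) {
    if (i <= world$cache$next_id)
      world$cache$info[[i]]$count <- as.integer(res$sp_count[i])
  }
  cn <- c("time", world$obs_names,
          if (!is.null(world$hybrid)) world$hybrid$name else NULL)
  cm <- res$counts
  colnames(cm) <- cn
  world$counts <- if (is.null(world$counts)) cm else rbind(world$counts, cm)
  if (!is.null(world$hybrid) && !is.null(res$hybrid_value))
    world$hybrid$value <- res$hybrid_value
  # clear one-shot releases that have fired
  world$pending_releases <- Filter(function(r) r$iter >= world$iter,
                                   world$pending_releases)
  invisible(world)
}

#' Release molecules from a site into a world
#'
#' The release is queued as a ReleaseEvent for the world's next iteration
#' (events execute in the fixed per-iteration order), so it takes effect on
#' the next [run_iterations()] call.
#'
#' @param world an `mc_world`.
#' @param site an `mc_release_site`.
#' @return the world, invisibly.
#' @export
release_molecules <- function(world, site) {
  site$time <- world$time + site$time
  queue_release(world, site)
  invisible(world)
}

#' Register a reaction or wall-hit callback
#'
#' Reaction callbacks run synchronously whenever the named rule fires and
#' receive (time, rule index, position, context); returning
#' `list(create = list(sp =, x =, y =, z =))` creates volume molecules at
#' the given positions. Wall-hit callbacks receive (time, species id,
#' triangle, hit point, context).
#'
#' @param world an `mc_world`.
#' @param kind `"reaction"` or `"wall_hit"`.
#' @param trigger rule name (reaction callbacks).
#' @param fn callback function.
#' @param context arbitrary context object passed through.
#' @param species,object optional wall-hit filters.
#' @return invisible handle (index).
#' @export
register_callback <- function(world, kind = c("reaction", "wall_hit"),
                              trigger = NULL, fn, context = NULL,
                              species = NULL, object = NULL) {
  kind <- match.arg(kind)
  if (kind == "reaction" && !is.null(trigger) &&
      !trigger %in% world$rule_names)
    stop("unknown rule '", trigger, "'")
  if (kind == "wall_hit" && !is.null(object) && !is.null(world$geom) &&
      !object %in% world$geom$obj_names)
    stop("unknown geometry object '", object, "'")
  world$callbacks[[length(world$callbacks) + 1L]] <-
    list(kind = kind, trigger = trigger, fn = fn, context = context,
         species = species, object = object)
  invisible(length(world$callbacks))
}

#' Current molecule table of a world
#' @param world an `mc_world`.
#' @return data frame with id, species label, kind, position / tile info.
#' @export
molecule_table <- function(world) {
  lab <- function(ids) vapply(ids, function(i)
    species_label(world$cache, i), "")
  v <- world$vol; s <- world$surf
  rbind(
    if (length(v$id)) data.frame(id = v$id, species = lab(v$sp),
                                 kind = "volume", x = v$x, y = v$y, z = v$z,
                                 triangle = NA_integer_, tile = NA_integer_,
                                 stringsAsFactors = FALSE),
    if (length(s$id)) {
      pos <- t(vapply(seq_along(s$id), function(k) {
        grid_like <- list(mesh = world$geom$mesh, n = world$geom$tri_n)
        tile_center(grid_like, s$tri[k], s$tile[k])
      }, numeric(3)))
      data.frame(id = s$id, species = lab(s$sp), kind = "surface",
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 triangle = s$tri, tile = s$tile, stringsAsFactors = FALSE)
    })
}

#' Run-summary of reaction probabilities and missed reactions
#'
#' Reports, per rule, the maximum per-collision probability seen, the number
#' of collision tests, and the estimated fraction of missed reactions caused
#' by probabilities above 1.
#'
#' @param world an `mc_world` after [run_iterations()].
#' @return data frame.
#' @export
probability_report <- function(world) {
  if (is.null(world$pstats)) return(data.frame())
  data.frame(rule = world$rule_names,
             max_p = world$pstats[, 1],
             tests = world$pstats[, 2],
             missed_fraction = ifelse(world$pstats[, 3] > 0,
                                      world$pstats[, 4] / world$pstats[, 3], 0),
             stringsAsFactors = FALSE)
}

#' @export
print.mc_world <- function(x, ...) {
  cat("<mc_world> t =", format(x$time), "s, iteration", x$iter, "-",
      length(x$vol$id), "volume +", length(x$surf$id),
      "surface molecules,", x$cache$next_id, "species known\n")
  invisible(x)
}
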