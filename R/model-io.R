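# Model assembly: bundles combining BNGL chemistry with geometry, releases,
# observables and run configuration; gdat-style count output; ASCII
# visualization frames; and a thin command-line runner.

#' Assemble a model bundle
#'
#' A bundle holds everything a world needs: the BNGL model (parameters,
#' molecule types, compartments, seeds, observables, rules), geometry
#' objects, extra release sites, species-selective surface classes, event
#' callbacks, an optional hybrid-species specification, and the simulation
#' configuration.
#'
#' @param bngl a `bngl_model`.
#' @param geometry list of [geometry_object()]s.
#' @param releases list of [release_site()]s (besides the BNGL seed species).
#' @param observables optional list overriding the BNGL observables; each
#'   entry is `list(kind, name, patterns, scope, count_rule)` where `scope`
#'   is a compartment name (or `NA` for the whole world) and `count_rule`
#'   turns the observable into a cumulative reaction-occurrence counter.
#' @param config an [simulation_config()].
#' @param surface_classes list of `list(species =, object =, region =,
#'   behavior =)` with behavior `"reflective"`, `"transparent"` or
#'   `"absorptive"`; `species = NULL` applies to all species.
#' @param callbacks initial callback registrations (see
#'   [register_callback()]).
#' @param hybrid optional hybrid continuous-species spec, see
#'   [hybrid_species()].
#' @return list of class `mc_model_bundle`.
#' @export
model_bundle <- function(bngl, geometry = list(), releases = list(),
                         observables = NULL, config = simulation_config(),
                         surface_classes = list(), callbacks = list(),
                         hybrid = NULL) {
  if (is.null(observables)) {
    observables <- lapply(bngl$observables, function(o) {
      o$scope <- NA_character_; o$count_rule <- NA_character_; o
    })
  }
  structure(list(bngl = bngl, geometry = geometry, releases = releases,
                 observables = observables, config = config,
                 surface_classes = surface_classes, callbacks = callbacks,
                 hybrid = hybrid),
            class = "mc_model_bundle")
}

#' Specification of a hybrid continuous species
#'
#' One species is tracked as a continuous copy number R(t) instead of as
#' particles, updated each iteration by an explicit Euler step with the
#' particle time step:
#' R <- R + dt * (sum(prod_i * n_i) - decay * R - sum(cons_j * R * n_j))
#'       + (firings of `gain_rules` this iteration),
#' and the pseudo-first-order rate of `coupled_rule` is set to
#' `coupled_coef * R(t)` before the next iteration.
#'
#' @param name column name of the continuous value in count output.
#' @param value0 initial copy number.
#' @param decay first-order decay rate (1/s).
#' @param prod named numeric: production coefficients per driving species
#'   (names are BNGL species strings).
#' @param cons named numeric: consumption coefficients (pseudo-first-order
#'   per molecule of the named species).
#' @param gain_rules rule names whose firings add +1 to R.
#' @param coupled_rule unimolecular rule whose rate is `coupled_coef * R`.
#' @param coupled_coef coupling coefficient (1/s per copy of R).
#' @return list used as the `hybrid` slot of [model_bundle()].
#' @export
hybrid_species <- function(name, value0, decay, prod = numeric(),
                           cons = numeric(), gain_rules = character(),
                           coupled_rule, coupled_coef) {
  list(name = name, value = value0, decay = decay, prod = prod, cons = cons,
       gain_rules = gain_rules, coupled_rule = coupled_rule,
       coupled_coef = coupled_coef)
}

#' Load a BNGL file into a spatial model bundle
#'
#' Optionally imports only selected sections, and replaces BNGL compartments
#' with actual 3D geometry: a compartment named in `compartment_map` uses
#' the given mesh (its enclosed volume must agree with the declared
#' compartment size within 1 percent); any other 3D compartment gets an
#' auto-generated box of matching volume (a 2D parent compartment becomes
#' the box surface).
#'
#' @param path a `.bngl` file (or BNGL text).
#' @param sections `"all"` or a character vector among `"parameters"`,
#'   `"molecule types"`, `"compartments"`, `"seed species"`,
#'   `"observables"`, `"reaction rules"`.
#' @param compartment_map named list: 3D compartment name -> `mc_mesh`.
#' @param config an [simulation_config()].
#' @param into optional existing bundle to import the selected sections
#'   into.
#' @return an `mc_model_bundle`.
#' @export
load_bngl_into_model <- function(path, sections = "all",
                                 compartment_map = list(),
                                 config = simulation_config(), into = NULL) {
  m <- parse_bngl(path)
  all_secs <- c("parameters", "molecule types", "compartments",
                "seed species", "observables", "reaction rules")
  secs <- if (identical(sections, "all")) all_secs else sections
  bad <- setdiff(secs, all_secs)
  if (length(bad)) stop("unknown section(s): ", paste(bad, collapse = ", "))
  field_of <- c("parameters" = "parameters",
                "molecule types" = "molecule_types",
                "compartments" = "compartments",
                "seed species" = "seed_species",
                "observables" = "observables",
                "reaction rules" = "reaction_rules")
  if (!is.null(into)) {
    base <- into$bngl
    for (s in secs) base[[field_of[[s]]]] <- m[[field_of[[s]]]]
    into$bngl <- base
    if ("observables" %in% secs)
      into$observables <- lapply(base$observables, function(o) {
        o$scope <- NA_character_; o$count_rule <- NA_character_; o
      })
    return(into)
  }
  keep <- empty_bngl_model()
  for (s in secs) keep[[field_of[[s]]]] <- m[[field_of[[s]]]]
  geometry <- list()
  comps <- keep$compartments
  vols3d <- names(comps)[vapply(comps, function(c) c$dim == 3L, logical(1))]
  for (nm in vols3d) {
    surf <- NA_character_
    par <- comps[[nm]]$parent
    if (!is.null(par) && !is.na(par) && comps[[par]]$dim == 2L) surf <- par
    if (!is.null(compartment_map[[nm]])) {
      mesh <- compartment_map[[nm]]
      mv <- mesh_measures(mesh)$volume
      if (abs(mv - comps[[nm]]$size) / comps[[nm]]$size > 0.01)
        stop("mesh volume ", signif(mv, 6), " um^3 does not match declared ",
             "size of compartment '", nm, "' (", comps[[nm]]$size,
             " um^3) within 1%")
    } else {
      enclosed <- comps[[nm]]$size
      # an auto-box for an outer compartment must also enclose its children
      kids3d <- names(comps)[vapply(comps, function(c) {
        !is.na(c$parent) && !is.null(comps[[c$parent]]) &&
          identical(comps[[c$parent]]$parent, nm)
      }, logical(1))]
      enclosed <- enclosed + sum(vapply(kids3d, function(k)
        comps[[k]]$size, 0))
      mesh <- make_box(c(0, 0, 0), rep(enclosed^(1 / 3), 3L))
    }
    geometry[[length(geometry) + 1L]] <-
      geometry_object(mesh, name = nm, inside_compartment = nm,
                      surface_compartment = surf)
  }
  model_bundle(keep, geometry = geometry, config = config)
}

## ---------------------------------------------------------------------------
## Observables

#' Evaluate an observable against the current world state
#'
#' `Molecules` observables sum pattern embeddings over all molecule
#' instances; `Species` observables count instances whose species matches at
#' least one pattern; an observable with a `count_rule` returns the
#' cumulative number of firings of that rule.
#'
#' @param world an `mc_world`.
#' @param obs observable entry: `list(kind, name, patterns, scope,
#'   count_rule)`; patterns may be BNGL strings or `mc_complex`.
#' @return numeric count.
#' @export
count_observable <- function(world, obs) {
  if (!is.na(obs$count_rule %||% NA_character_)) {
    ri <- match(obs$count_rule, world$rule_names)
    if (is.na(ri)) stop("unknown rule '", obs$count_rule, "'")
    return(world$fired[ri])
  }
  pats <- lapply(obs$patterns, function(p)
    if (inherits(p, "mc_complex")) p else parse_complex(p, world$types))
  scope_id <- 0L
  sc <- obs$scope %||% NA_character_
  if (!is.na(sc)) scope_id <- world$comp_ids[[sc]] %||% 0L
  weight <- function(sp_id) {
    g <- species_graph(world$cache, sp_id)
    val <- 0
    for (p in pats) {
      ne <- length(match_pattern(p, g))
      if (obs$kind == "Species") { if (ne > 0) return(1) }
      else val <- val + ne
    }
    val
  }
  sp_ids <- unique(c(world$vol$sp, world$surf$sp))
  wts <- stats::setNames(vapply(sp_ids, weight, 0), sp_ids)
  tot <- 0
  for (k in seq_along(world$vol$sp)) {
    if (scope_id != 0L && world$vol$comp[k] != scope_id) next
    tot <- tot + wts[[as.character(world$vol$sp[k])]]
  }
  for (k in seq_along(world$surf$sp)) {
    if (scope_id != 0L) {
      spc <- world$cache$info[[world$surf$sp[k]]]$compartment
      if (is.na(spc) || (world$comp_ids[[spc]] %||% 0L) != scope_id) next
    }
    tot <- tot + wts[[as.character(world$surf$sp[k])]]
  }
  tot
}

## ---------------------------------------------------------------------------
## gdat and viz output

#' Write observable time series as a gdat table
#'
#' Whitespace-delimited scientific-notation columns with a `#   time ...`
#' header, 15 significant digits (the BioNetGen gdat convention).
#'
#' @param series numeric matrix whose first column is time (the `counts`
#'   matrix of a world), with column names.
#' @param path output file.
#' @export
write_gdat <- function(series, path) {
  cn <- colnames(series)
  if (is.null(cn)) cn <- c("time", paste0("obs", seq_len(ncol(series) - 1L)))
  header <- paste0("# ", paste(formatC(cn, width = 22), collapse = " "))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  if (nrow(series)) {
    rows <- apply(series, 1L, function(r)
      paste0("  ", paste(formatC(r, format = "e", digits = 14, width = 22),
                         collapse = " ")))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a gdat table
#' @param path gdat file.
#' @return numeric matrix with column names from the header.
#' @export
read_gdat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[1]
  cn <- strsplit(trimws(sub("^#", "", header)), "[[:space:]]+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    m <- matrix(numeric(), 0L, length(cn))
    colnames(m) <- cn
    return(m)
  }
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  colnames(m) <- cn
  m
}

#' Write an ASCII visualization frame
#'
#' One row per molecule: species name, id, x y z (um); surface molecules
#' additionally carry their triangle normal vector.
#'
#' @param world an `mc_world`.
#' @param iteration iteration number stamped into the header.
#' @param path output file.
#' @export
write_viz_frame <- function(world, iteration, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# iteration %d time %.9g", iteration, world$time), con)
  tab <- molecule_table(world)
  if (!is.null(tab) && nrow(tab)) {
    for (k in seq_len(nrow(tab))) {
      if (tab$kind[k] == "surface") {
        v <- tri_vertices(world$geom$mesh, tab$triangle[k])
        n <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
        n <- n / sqrt(sum(n^2))
        writeLines(sprintf("%s %d %.9g %.9g %.9g %.6g %.6g %.6g",
                           tab$species[k], tab$id[k], tab$x[k], tab$y[k],
                           tab$z[k], n[1], n[2], n[3]), con)
      } else {
        writeLines(sprintf("%s %d %.9g %.9g %.9g", tab$species[k],
                           tab$id[k], tab$x[k], tab$y[k], tab$z[k]), con)
      }
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Command line entry point

#' Run a model from a structured-text configuration
#'
#' The configuration is YAML with keys `model` (BNGL file), and optional
#' `iterations`, `dt`, `seed`, `grid_density`, `count_stride`, `units`,
#' `cleanup_interval`, `output` (gdat path). Flags:
#' `run <config> [--seed S] [--iterations N] [--dt T] [--out DIR]
#' [--export-bngl PATH] [--expand-network]`.
#'
#' @param args character vector of command-line arguments.
#' @return exit code, 0 on success.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: run <config.yaml> [--seed S] [--iterations N] [--dt T]",
            " [--out DIR] [--export-bngl PATH] [--expand-network]")
    1L
  }
  tryCatch({
    if (!length(args) || args[1] != "run") return(usage())
    cfgfile <- NULL; overrides <- list(); outdir <- "."
    export_bngl <- NULL; do_expand <- FALSE
    i <- 2L
    while (i <= length(args)) {
      a <- args[i]
      if (a == "--seed") { overrides$seed <- as.numeric(args[i + 1]); i <- i + 2L }
      else if (a == "--iterations") { overrides$iterations <- as.integer(args[i + 1]); i <- i + 2L }
      else if (a == "--dt") { overrides$dt <- as.numeric(args[i + 1]); i <- i + 2L }
      else if (a == "--out") { outdir <- args[i + 1]; i <- i + 2L }
      else if (a == "--export-bngl") { export_bngl <- args[i + 1]; i <- i + 2L }
      else if (a == "--expand-network") { do_expand <- TRUE; i <- i + 1L }
      else if (startsWith(a, "--")) { message("unknown flag ", a); return(usage()) }
      else if (is.null(cfgfile)) { cfgfile <- a; i <- i + 1L }
      else { message("unexpected argument ", a); return(usage()) }
    }
    if (is.null(cfgfile)) return(usage())
    cfg <- yaml::read_yaml(cfgfile)
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
    message("model: ", cfg$model)
    sc <- simulation_config(
      dt = cfg$dt %||% 1e-6, seed = cfg$seed %||% 1,
      grid_density = cfg$grid_density %||% 1e4,
      cleanup_interval = cfg$cleanup_interval %||% 10000L,
      count_stride = cfg$count_stride %||% 1L,
      units = cfg$units %||% "mcell")
    message("seed: ", sc$seed, "  dt: ", sc$dt, " s  iterations: ",
            cfg$iterations %||% 0L)
    bundle <- load_bngl_into_model(
      file.path(dirname(cfgfile), cfg$model), config = sc)
    if (!is.null(export_bngl)) {
      txt <- write_bngl(bundle, export_bngl)
      for (wn in attr(txt, "warnings")) message("export: ", wn)
      message("exported BNGL to ", export_bngl)
    }
    if (do_expand) {
      net <- expand_network(bundle$bngl)
      netfile <- file.path(outdir, "network.net")
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_net(net, netfile)
      message("expanded network: ", nrow(net$species), " species, ",
              nrow(net$reactions), " reactions -> ", netfile)
    }
    iters <- cfg$iterations %||% 0L
    if (iters > 0L) {
      w <- build_world(bundle)
      run_iterations(w, iters)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      out <- file.path(outdir, cfg$output %||% "counts.gdat")
      write_gdat(w$counts, out)
      message("wrote ", out)
      pr <- probability_report(w)
      high <- pr[pr$max_p > 1, , drop = FALSE]
      for (k in seq_len(nrow(high)))
        message(sprintf("warning: rule %s reached p = %.3g (est. missed fraction %.3g)",
                        high$rule[k], high$max_p[k], high$missed_fraction[k]))
      for (wn in unique(w$warnings)) message("warning: ", wn)
      message("final molecules: ",
              length(w$vol$id) + length(w$surf$id))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
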