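# Network-free species/reaction caches and bounded full network expansion.
# Species are cached under their canonical label; reaction classes (the
# concrete pathways applicable to a species pair) are computed on first
# lookup by matching every rule against the pair and are cached. Caches are
# periodically cleaned of species with no live molecules; ids are never
# reused, so cleanup cannot perturb a trajectory.

#' Create an empty species cache
#'
#' @return an environment holding the label->id map, per-id species records
#'   and the reaction-class cache.
#' @export
species_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$by_label <- new.env(parent = emptyenv())
  e$info <- list()          # id -> record
  e$rxn <- new.env(parent = emptyenv())  # "u:i" / "b:i:j" -> RxnClass
  e$next_id <- 0L
  class(e) <- "mc_species_cache"
  e
}

#' Register a species graph in the cache
#'
#' Canonicalizes the graph; an already-known label returns its existing id
#' (ids are stable for the lifetime of the cache, surviving cleanup).
#'
#' @param cache a species cache.
#' @param g an `mc_complex` species.
#' @param types molecule type table (used to derive the complex diffusion
#'   constant; omit for pure counting applications).
#' @return integer species id.
#' @export
register_species <- function(cache, g, types = NULL) {
  lab <- canonical_form(g)
  id <- cache$by_label[[lab]]
  if (!is.null(id)) {
    if (is.null(cache$info[[id]]$graph)) {   # evicted: refill heavy fields
      rec <- cache$info[[id]]
      rec$graph <- g
      cache$info[[id]] <- rec
    }
    return(id)
  }
  D <- NA_real_; dim <- 3L
  if (!is.null(types)) {
    ok <- !any(vapply(g$mol_type, function(t)
      is.null(types[[t]]) || is.na(types[[t]]$D), logical(1)))
    if (ok) {
      dd <- derive_diffusion_constant(g, types)
      D <- dd$D; dim <- dd$dim
    } else {
      dim <- if (graph_is_surface(g, types)) 2L else 3L
    }
  }
  id <- cache$next_id + 1L
  cache$next_id <- id
  cache$by_label[[lab]] <- id
  cache$info[[id]] <- list(id = id, label = lab, graph = g, D = D, dim = dim,
                           compartment = g$compartment, count = 0L)
  id
}

#' Canonical label / graph of a cached species id
#' @param cache a species cache.
#' @param id integer species id.
#' @return label string, or the `mc_complex` graph.
#' @export
species_label <- function(cache, id) cache$info[[id]]$label

#' @rdname species_label
#' @export
species_graph <- function(cache, id) cache$info[[id]]$graph

pattern_key <- function(g) {
  paste0(serialize_complex(g, seq_len(n_mols(g)), comp_order_given = TRUE),
         if (!is.na(g$compartment)) paste0("@", g$compartment) else "")
}

#' Look up (or compute and cache) the reaction class of a species pair
#'
#' On first call, every rule's reactant patterns are matched against the pair
#' in both orderings; each pattern-automorphism-distinct embedding contributes
#' one pathway at the rule's full rate constant. For a pair of identical
#' species under a rule with two identical reactant patterns, the swapped
#' ordering is the same event and is not double counted. The result is
#' cached; later calls return the cached object.
#'
#' @param cache a species cache.
#' @param ids integer vector of 1 (unimolecular class) or 2 species ids.
#' @param rules list of `mc_rule` (unidirectional).
#' @param types molecule type table.
#' @return an `mc_rxn_class`: list with `reactants` and `pathways`; each
#'   pathway has `rule`, `rate`, `context` and `products` (species ids).
#' @export
lookup_or_expand <- function(cache, ids, rules, types = NULL) {
  ids <- as.integer(ids)
  key <- if (length(ids) == 1L) paste0("u:", ids)
         else paste0("b:", min(ids), ":", max(ids))
  hit <- cache$rxn[[key]]
  if (!is.null(hit)) return(hit)
  cls <- compute_rxn_class(cache, sort(ids), rules, types)
  cache$rxn[[key]] <- cls
  cls
}

compute_rxn_class <- function(cache, ids, rules, types) {
  pathways <- list()
  add <- function(rule, embs, reactant_ids, dup = 1L) {
    for (e in embs) {
      prods <- apply_rule(rule, lapply(reactant_ids, species_graph,
                                       cache = cache), e, types)
      pid <- vapply(prods, register_species, 0L, cache = cache, types = types)
      for (d in seq_len(dup))
        pathways[[length(pathways) + 1L]] <<- list(
          rule = rule$name, rate = rule$rate,
          context = rule_context(rule, types), products = as.integer(pid))
    }
  }
  for (rule in rules) {
    if (length(rule$reactants) != length(ids)) next
    if (length(ids) == 1L) {
      add(rule, rule_embeddings(rule, list(species_graph(cache, ids))), ids)
    } else {
      sym_rule <- pattern_key(rule$reactants[[1L]]) ==
                  pattern_key(rule$reactants[[2L]])
      gi <- species_graph(cache, ids[1L]); gj <- species_graph(cache, ids[2L])
      if (ids[1L] == ids[2L]) {
        add(rule, rule_embeddings(rule, list(gi, gj)), ids,
            dup = if (sym_rule) 1L else 2L)
      } else {
        add(rule, rule_embeddings(rule, list(gi, gj)), ids)
        if (!sym_rule)
          add(rule, rule_embeddings(rule, list(gj, gi)), rev(ids))
        else {
          # identical patterns: the swapped ordering is the same event set
          # only when it reproduces the first; in general patterns equal
          # means ordering (j,i) duplicates (i,j)
          NULL
        }
      }
    }
  }
  structure(list(reactants = ids, pathways = pathways),
            class = "mc_rxn_class")
}

#' Evict zero-instance species and their reaction classes from the caches
#'
#' Heavy per-species data (the graph) and every cached reaction class that
#' references an evicted species are dropped; the label->id map is retained
#' so a reappearing species gets its old id back and trajectories are
#' unaffected by cleanup.
#'
#' @param cache a species cache with up-to-date instance `count`s.
#' @return number of evicted species plus evicted reaction classes.
#' @export
cleanup_caches <- function(cache) {
  dead <- which(vapply(cache$info, function(r)
    !is.null(r$graph) && r$count == 0L, logical(1)))
  for (id in dead) {
    rec <- cache$info[[id]]
    rec$graph <- NULL
    cache$info[[id]] <- rec
  }
  evicted_cls <- 0L
  if (length(dead)) {
    for (key in ls(cache$rxn)) {
      cls <- cache$rxn[[key]]
      refs <- c(cls$reactants, unlist(lapply(cls$pathways, `[[`, "products")))
      if (any(refs %in% dead)) {
        rm(list = key, envir = cache$rxn)
        evicted_cls <- evicted_cls + 1L
      }
    }
  }
  length(dead) + evicted_cls
}

#' Fully expand the reaction network of a model (bounded)
#'
#' Fixed-point iteration from the seed species: every species pair (and every
#' single species) is matched against every rule until no new species appear.
#' Intended as a validation utility for models with finite, desk-scale
#' networks; the simulator itself never expands the full network.
#'
#' @param model a `bngl_model`.
#' @param max_species,max_reactions expansion limits; exceeding either raises
#'   a bounded-expansion error.
#' @param seeds optional character vector of BNGL complex strings overriding
#'   the model's seed species (useful for fixtures whose initial state is
#'   defined by spatial release sites).
#' @return object of class `mc_network`: list with `species` (data frame:
#'   id, label) and `reactions` (data frame: reactant ids `r1`,`r2` (NA for
#'   unimolecular), product id columns collapsed into a `products` string,
#'   `rate`, `context`, `rule`), deduplicated by (reactants, products, rule)
#'   with rate accumulated over duplicate embeddings.
#' @export
expand_network <- function(model, max_species = 5000L,
                           max_reactions = 50000L, seeds = NULL) {
  cache <- species_cache()
  types <- model$molecule_types
  rules <- model$reaction_rules
  seed_graphs <- if (is.null(seeds)) lapply(model$seed_species, `[[`, "graph")
                 else lapply(seeds, parse_complex, types = types)
  seeds <- unique(vapply(seed_graphs, function(g)
    register_species(cache, g, types), 0L))
  known <- integer(0)
  frontier <- sort(seeds)
  rxn_keys <- character(); rxn_list <- list()
  add_rxn <- function(reactants, pw) {
    key <- paste(paste(sort(reactants), collapse = ","),
                 paste(sort(pw$products), collapse = ","), pw$rule, sep = "|")
    if (key %in% names(rxn_list)) {
      rxn_list[[key]]$rate <<- rxn_list[[key]]$rate + pw$rate
      rxn_list[[key]]$multiplicity <<- rxn_list[[key]]$multiplicity + 1L
    } else {
      rxn_list[[key]] <<- list(reactants = sort(reactants),
                               products = sort(pw$products), rate = pw$rate,
                               context = pw$context, rule = pw$rule,
                               multiplicity = 1L)
    }
    if (length(rxn_list) > max_reactions)
      stop("bounded expansion exceeded: more than ", max_reactions,
           " reactions")
  }
  while (length(frontier)) {
    s <- frontier[1L]; frontier <- frontier[-1L]
    if (s %in% known) next
    known <- c(known, s)
    if (length(known) > max_species)
      stop("bounded expansion exceeded: more than ", max_species, " species")
    pairsets <- c(list(s), lapply(known, function(k) sort(c(s, k))))
    for (ids in pairsets) {
      cls <- lookup_or_expand(cache, ids, rules, types)
      for (pw in cls$pathways) {
        add_rxn(ids, pw)
        newids <- setdiff(pw$products, c(known, frontier))
        if (length(newids)) frontier <- c(frontier, newids)
      }
    }
    frontier <- sort(unique(frontier))
  }
  ids <- sort(known)
  species <- data.frame(
    id = ids,
    label = vapply(ids, species_label, "", cache = cache),
    stringsAsFactors = FALSE)
  if (length(rxn_list)) {
    reactions <- data.frame(
      r1 = vapply(rxn_list, function(r) r$reactants[1L], 0L),
      r2 = vapply(rxn_list, function(r)
        if (length(r$reactants) > 1L) r$reactants[2L] else NA_integer_, 0L),
      products = vapply(rxn_list, function(r)
        paste(r$products, collapse = ","), ""),
      rate = vapply(rxn_list, function(r) r$rate, 0),
      multiplicity = vapply(rxn_list, function(r) r$multiplicity, 0L),
      context = vapply(rxn_list, function(r) r$context, ""),
      rule = vapply(rxn_list, function(r) r$rule, ""),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    reactions <- data.frame(r1 = integer(), r2 = integer(),
                            products = character(), rate = numeric(),
                            multiplicity = integer(), context = character(),
                            rule = character(), stringsAsFactors = FALSE)
  }
  structure(list(species = species, reactions = reactions, cache = cache),
            class = "mc_network")
}

#' Write an expanded network as a plain-text reaction list
#'
#' Emits a species index table followed by reaction triples
#' (reactants, products, rate), in the spirit of BioNetGen `.net` files.
#'
#' @param net an `mc_network`.
#' @param path output file.
#' @export
write_net <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("begin species", con)
  writeLines(sprintf("  %d %s", net$species$id, net$species$label), con)
  writeLines(c("end species", "begin reactions"), con)
  if (nrow(net$reactions)) {
    lhs <- ifelse(is.na(net$reactions$r2), as.character(net$reactions$r1),
                  paste(net$reactions$r1, net$reactions$r2, sep = ","))
    writeLines(sprintf("  %s -> %s %.17g # %s", lhs, net$reactions$products,
                       net$reactions$rate, net$reactions$rule), con)
  }
  writeLines("end reactions", con)
  invisible(path)
}

#' @export
print.mc_network <- function(x, ...) {
  cat("<mc_network>", nrow(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  invisible(x)
}
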