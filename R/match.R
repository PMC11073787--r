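# Pattern matching (embedding enumeration) and rule application by graph
# rewriting. An embedding maps every pattern molecule and pattern component
# onto a molecule/component of the target graph, respecting molecule type
# names, component names, set states, and bond constraints. Embeddings that
# are equivalent under an automorphism of the pattern are collapsed.

#' Enumerate embeddings of a pattern into a species graph
#'
#' @param p an `mc_complex` pattern.
#' @param s an `mc_complex` species (or pattern, for automorphism search).
#' @param exact match labels exactly (unset state matches only unset state,
#'   wildcards match only the same wildcard); used internally to compute
#'   pattern automorphisms.
#' @param collapse_automorphisms drop embeddings equivalent under a pattern
#'   automorphism (default `TRUE`).
#' @return list of embeddings; each is a list with integer vectors `mol`
#'   (pattern molecule -> target molecule) and `comp` (pattern component ->
#'   target component, `NA` for pattern molecules listing no components).
#' @export
match_pattern <- function(p, s, exact = FALSE, collapse_automorphisms = TRUE) {
  if (!is.na(p$compartment) && !p$compartment %in% c("IN", "OUT")) {
    if (is.na(s$compartment) || s$compartment != p$compartment)
      return(list())
  }
  embs <- enumerate_embeddings(p, s, exact)
  if (!length(embs) || !collapse_automorphisms || n_mols(p) == 0L)
    return(embs)
  auts <- enumerate_embeddings(p, p, exact = TRUE)
  if (length(auts) <= 1L) return(embs)
  seen <- character(); out <- list()
  for (e in embs) {
    key <- min(vapply(auts, function(a) {
      cm <- e$comp[a$comp]
      paste(paste(e$mol[a$mol], collapse = ","),
            paste(ifelse(is.na(cm), 0L, cm), collapse = ","), sep = ";")
    }, character(1)))
    if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- e }
  }
  out
}

enumerate_embeddings <- function(p, s, exact = FALSE) {
  np <- n_mols(p); ns <- n_mols(s)
  if (np == 0L) return(list())
  if (np > ns) return(list())
  p_comps <- split(seq_along(p$comp_mol), factor(p$comp_mol, levels = seq_len(np)))
  s_comps <- split(seq_along(s$comp_mol), factor(s$comp_mol, levels = seq_len(ns)))
  p_partner <- bond_partner(p)
  s_partner <- bond_partner(s)
  results <- list()
  molmap <- rep(NA_integer_, np)
  compmap <- rep(NA_integer_, length(p$comp_mol))
  used_mol <- logical(ns)

  comp_ok <- function(pc, sc) {
    if (p$comp_name[pc] != s$comp_name[sc]) return(FALSE)
    pst <- p$comp_state[pc]; sst <- s$comp_state[sc]
    if (exact) {
      if (!identical(is.na(pst), is.na(sst))) return(FALSE)
      if (!is.na(pst) && pst != sst) return(FALSE)
    } else if (!is.na(pst) && (is.na(sst) || pst != sst)) return(FALSE)
    pb <- p$comp_bond[pc]; sb <- s$comp_bond[sc]
    if (exact) {
      if ((pb > 0L) != (sb > 0L)) return(FALSE)
      if (pb <= 0L && pb != sb) return(FALSE)
    } else {
      if (pb == BOND_NONE && sb != BOND_NONE) return(FALSE)
      if (pb == BOND_EXISTS && sb <= 0L) return(FALSE)
      if (pb > 0L && sb <= 0L) return(FALSE)
      # BOND_ANY matches anything
    }
    # explicit pattern bond: if the pattern partner is already mapped, the
    # target comps must be bonded to each other
    if (pb > 0L) {
      pp <- p_partner[pc]
      if (!is.na(pp) && !is.na(compmap[pp]) && (is.na(s_partner[sc]) ||
            s_partner[sc] != compmap[pp])) return(FALSE)
    }
    TRUE
  }

  try_mol <- function(pm) {
    if (pm > np) {
      results[[length(results) + 1L]] <<- list(mol = molmap, comp = compmap)
      return(invisible())
    }
    pcs <- p_comps[[pm]]
    for (sm in seq_len(ns)) {
      if (used_mol[sm] || p$mol_type[pm] != s$mol_type[sm]) next
      scs <- s_comps[[sm]]
      if (exact && length(scs) != length(pcs)) next
      if (length(scs) < length(pcs)) next
      molmap[pm] <<- sm; used_mol[sm] <<- TRUE
      assign_comps(pm, pcs, scs, 1L, logical(length(scs)))
      molmap[pm] <<- NA_integer_; used_mol[sm] <<- FALSE
    }
  }

  assign_comps <- function(pm, pcs, scs, k, used) {
    if (k > length(pcs)) { try_mol(pm + 1L); return(invisible()) }
    pc <- pcs[k]
    for (j in seq_along(scs)) {
      if (used[j]) next
      sc <- scs[j]
      if (!comp_ok(pc, sc)) next
      compmap[pc] <<- sc
      used[j] <- TRUE
      assign_comps(pm, pcs, scs, k + 1L, used)
      used[j] <- FALSE
      compmap[pc] <<- NA_integer_
    }
  }

  try_mol(1L)
  results
}

## ---------------------------------------------------------------------------

#' Construct a reaction rule
#'
#' A rule is a graph transformation on one or two reactant patterns. The
#' reactant->product correspondence follows the BNGL positional convention:
#' the i-th occurrence of a molecule type on the product side corresponds to
#' the i-th occurrence on the reactant side (components by name occurrence
#' within the molecule); unmatched reactant molecules are deleted, unmatched
#' product molecules are created.
#'
#' @param name rule name.
#' @param reactants list of 1 or 2 `mc_complex` patterns.
#' @param products list of `mc_complex` patterns (may be empty: degradation).
#' @param rate rate constant (units per the simulation unit system and the
#'   reaction context).
#' @return an object of class `mc_rule` with the computed mapping.
#' @export
mc_rule <- function(name, reactants, products, rate) {
  stopifnot(length(reactants) %in% 1:2, rate >= 0)
  r <- structure(list(name = name, reactants = reactants, products = products,
                      rate = rate), class = "mc_rule")
  r$mapping <- rule_mapping(r)
  r
}

# flatten molecules/components of a list of patterns, with offsets
flatten_patterns <- function(pats) {
  molt <- character(); cmol <- integer(); cname <- character()
  cstate <- character(); cbond <- integer(); sf <- logical()
  moloff <- integer(length(pats)); compoff <- integer(length(pats))
  pat_of_mol <- integer()
  for (i in seq_along(pats)) {
    g <- pats[[i]]
    moloff[i] <- length(molt); compoff[i] <- length(cname)
    bonds <- g$comp_bond
    bonds[bonds > 0L] <- bonds[bonds > 0L] + 1000L * i  # keep ids pattern-local
    molt <- c(molt, g$mol_type)
    cmol <- c(cmol, g$comp_mol + moloff[i])
    cname <- c(cname, g$comp_name); cstate <- c(cstate, g$comp_state)
    cbond <- c(cbond, bonds); sf <- c(sf, g$stateful)
    pat_of_mol <- c(pat_of_mol, rep(i, n_mols(g)))
  }
  list(g = new_complex(molt, cmol, cname, cstate, cbond, sf),
       moloff = moloff, compoff = compoff, pat_of_mol = pat_of_mol)
}

rule_mapping <- function(r) {
  L <- flatten_patterns(r$reactants)
  R <- flatten_patterns(if (length(r$products)) r$products else list())
  lg <- L$g; rg <- if (length(r$products)) R$g else
    new_complex(character(), integer(), character(), character(), integer(),
                logical())
  # molecule correspondence by type occurrence order
  mol_src <- rep(NA_integer_, n_mols(rg))
  for (ty in unique(rg$mol_type)) {
    li <- which(lg$mol_type == ty); ri <- which(rg$mol_type == ty)
    n <- min(length(li), length(ri))
    if (n) mol_src[ri[seq_len(n)]] <- li[seq_len(n)]
  }
  # component correspondence by name occurrence within corresponding molecules
  comp_src <- rep(NA_integer_, length(rg$comp_name))
  for (rm in seq_len(n_mols(rg))) {
    lm <- mol_src[rm]
    if (is.na(lm)) next
    rcs <- which(rg$comp_mol == rm); lcs <- which(lg$comp_mol == lm)
    for (nm in unique(rg$comp_name[rcs])) {
      ri <- rcs[rg$comp_name[rcs] == nm]
      li <- lcs[lg$comp_name[lcs] == nm]
      n <- min(length(ri), length(li))
      if (n) comp_src[ri[seq_len(n)]] <- li[seq_len(n)]
    }
  }
  list(lhs = L, rhs = R, mol_src = mol_src, comp_src = comp_src,
       deleted_mols = setdiff(seq_len(n_mols(lg)), mol_src[!is.na(mol_src)]))
}

disjoint_union <- function(graphs) {
  molt <- character(); cmol <- integer(); cname <- character()
  cstate <- character(); cbond <- integer(); sf <- logical()
  src_graph <- integer(); moloff <- integer(length(graphs))
  maxid <- 0L
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    moloff[i] <- length(molt)
    bonds <- g$comp_bond
    bonds[bonds > 0L] <- bonds[bonds > 0L] + maxid
    if (length(bonds)) maxid <- max(maxid, bonds, 0L)
    molt <- c(molt, g$mol_type)
    cmol <- c(cmol, g$comp_mol + moloff[i])
    cname <- c(cname, g$comp_name); cstate <- c(cstate, g$comp_state)
    cbond <- c(cbond, bonds); sf <- c(sf, g$stateful)
    src_graph <- c(src_graph, rep(i, n_mols(g)))
  }
  list(g = new_complex(molt, cmol, cname, cstate, cbond, sf),
       moloff = moloff, src_graph = src_graph)
}

#' Apply a reaction rule to concrete reactant species
#'
#' Performs the graph rewrite for one chosen embedding: state changes, bond
#' creation/deletion, molecule deletion and creation exactly as the rule's
#' reactant->product mapping prescribes. Each connected component of the
#' resulting graph is returned as one product species.
#'
#' @param r an `mc_rule`.
#' @param reactants list of `mc_complex` species, one per reactant pattern.
#' @param embedding an embedding of the rule's flattened reactant patterns
#'   into the disjoint union of `reactants`, as produced by
#'   [rule_embeddings()]; if `NULL` the first available embedding is used.
#' @param types molecule type table (required when the rule creates molecules
#'   whose unlisted components must be filled in).
#' @return list of product `mc_complex` species (connected components).
#' @export
apply_rule <- function(r, reactants, embedding = NULL, types = NULL) {
  if (length(reactants) != length(r$reactants))
    stop("rule '", r$name, "' expects ", length(r$reactants), " reactant(s)")
  if (is.null(embedding)) {
    embs <- rule_embeddings(r, reactants)
    if (!length(embs)) stop("reactants do not match rule '", r$name, "'")
    embedding <- embs[[1L]]
  }
  U <- disjoint_union(reactants)
  g <- U$g
  map <- r$mapping
  lg <- map$lhs$g
  emb_mol <- embedding$mol; emb_comp <- embedding$comp
  if (length(emb_mol) != n_mols(lg))
    stop("embedding does not cover the rule's reactant patterns")
  l_partner <- bond_partner(lg)
  rg <- if (length(r$products)) map$rhs$g else
    new_complex(character(), integer(), character(), character(), integer(),
                logical())
  r_partner <- bond_partner(rg)

  # --- state changes on mapped components
  for (rc in seq_along(rg$comp_name)) {
    lc <- map$comp_src[rc]
    if (is.na(lc)) next
    tc <- emb_comp[lc]
    if (is.na(tc)) next
    if (!is.na(rg$comp_state[rc]) &&
        !identical(rg$comp_state[rc], g$comp_state[tc]))
      g$comp_state[tc] <- rg$comp_state[rc]
  }

  next_bond <- max(c(0L, g$comp_bond))
  del_bond <- function(tc) {
    b <- g$comp_bond[tc]
    if (b > 0L) g$comp_bond[g$comp_bond == b] <<- BOND_NONE
  }
  # --- bond deletions: explicit lhs bond absent between the rhs images
  lhs_bonds <- bond_pairs(lg)
  if (nrow(lhs_bonds)) for (k in seq_len(nrow(lhs_bonds))) {
    lc1 <- lhs_bonds[k, 1L]; lc2 <- lhs_bonds[k, 2L]
    rc1 <- match(lc1, map$comp_src); rc2 <- match(lc2, map$comp_src)
    bonded_rhs <- !is.na(rc1) && !is.na(rc2) && rg$comp_bond[rc1] > 0L &&
      !is.na(r_partner[rc1]) && r_partner[rc1] == rc2
    if (!bonded_rhs) del_bond(emb_comp[lc1])
  }
  # --- lhs wildcard "+"/"?" with rhs explicitly unbound: break whatever bond
  for (lc in seq_along(lg$comp_name)) {
    if (lg$comp_bond[lc] >= 0L) next
    rc <- match(lc, map$comp_src)
    if (!is.na(rc) && rg$comp_bond[rc] == BOND_NONE) del_bond(emb_comp[lc])
  }
  # --- molecule deletions (their bonds die with them)
  del_target <- emb_mol[map$deleted_mols]
  if (length(del_target)) {
    for (tc in which(g$comp_mol %in% del_target)) del_bond(tc)
  }
  # --- molecule creations
  created_comp_of <- rep(NA_integer_, length(rg$comp_name))
  for (rm in which(is.na(map$mol_src))) {
    ty <- rg$mol_type[rm]
    decl <- if (!is.null(types)) types[[ty]] else NULL
    rcs <- which(rg$comp_mol == rm)
    if (is.null(decl)) {
      if (any(is.na(rg$comp_state[rcs]) & rg$stateful[rcs]))
        stop("created molecule '", ty, "' has unset states and no type table")
      newnames <- rg$comp_name[rcs]; newstates <- rg$comp_state[rcs]
      newsf <- rg$stateful[rcs]
      src_rc <- rcs
    } else {
      used <- integer(); src_rc <- rep(NA_integer_, length(decl$comp_names))
      newstates <- rep(NA_character_, length(decl$comp_names))
      for (rc in rcs) {
        slots <- setdiff(which(decl$comp_names == rg$comp_name[rc]), used)
        if (!length(slots))
          stop("created molecule '", ty, "' lists unknown component '",
               rg$comp_name[rc], "'")
        used <- c(used, slots[1L]); src_rc[slots[1L]] <- rc
        newstates[slots[1L]] <- rg$comp_state[rc]
      }
      # unlisted stateful components of a created molecule default to the
      # first declared state
      for (j in seq_along(decl$comp_names)) {
        if (is.na(src_rc[j]) && length(decl$comp_states[[j]]))
          newstates[j] <- decl$comp_states[[j]][1L]
      }
      newnames <- decl$comp_names
      newsf <- lengths(decl$comp_states) > 0L
      rcs <- src_rc
    }
    g$mol_type <- c(g$mol_type, ty)
    newm <- length(g$mol_type)
    for (j in seq_along(newnames)) {
      g$comp_mol <- c(g$comp_mol, newm)
      g$comp_name <- c(g$comp_name, newnames[j])
      g$comp_state <- c(g$comp_state, newstates[j])
      g$comp_bond <- c(g$comp_bond, BOND_NONE)
      g$stateful <- c(g$stateful, newsf[j])
      if (!is.na(rcs[j])) created_comp_of[rcs[j]] <- length(g$comp_name)
    }
  }
  # target component for each rhs component (mapped or newly created)
  rhs_target <- function(rc) {
    lc <- map$comp_src[rc]
    if (!is.na(lc)) return(emb_comp[lc])
    created_comp_of[rc]
  }
  # --- bond creations: explicit rhs bond not present between targets
  rhs_bonds <- bond_pairs(rg)
  if (nrow(rhs_bonds)) {
    g_partner <- bond_partner(g)
    for (k in seq_len(nrow(rhs_bonds))) {
      tc1 <- rhs_target(rhs_bonds[k, 1L]); tc2 <- rhs_target(rhs_bonds[k, 2L])
      if (is.na(tc1) || is.na(tc2))
        stop("rule '", r$name, "' bonds an unmapped component")
      already <- g$comp_bond[tc1] > 0L && !is.na(g_partner[tc1]) &&
        g_partner[tc1] == tc2
      if (!already) {
        if (g$comp_bond[tc1] > 0L || g$comp_bond[tc2] > 0L)
          stop("rule '", r$name, "' creates a bond on an occupied component")
        next_bond <- next_bond + 1L
        g$comp_bond[c(tc1, tc2)] <- next_bond
        g_partner <- bond_partner(g)
      }
    }
  }
  # --- drop deleted molecules
  if (length(del_target)) {
    keep_m <- setdiff(seq_along(g$mol_type), del_target)
    keep_c <- which(g$comp_mol %in% keep_m)
    g <- new_complex(g$mol_type[keep_m], match(g$comp_mol[keep_c], keep_m),
                     g$comp_name[keep_c], g$comp_state[keep_c],
                     g$comp_bond[keep_c], g$stateful[keep_c])
  }
  prods <- split_components(g)
  # product compartments: explicit rhs annotation wins (positionally, per
  # product pattern), else inherited from the reactants; when volume and
  # surface reactants mix, a surface product keeps the surface compartment
  # and a volume product the volume compartment
  rhs_comp <- vapply(r$products, function(p) p$compartment, character(1))
  rhs_comp[rhs_comp %in% c("IN", "OUT")] <- NA_character_
  in_comp <- unique(stats::na.omit(vapply(reactants, function(x)
    x$compartment, character(1))))
  in_surface <- vapply(reactants, function(x) graph_is_surface(x, types),
                       logical(1))
  for (i in seq_along(prods)) {
    cp <- if (i <= length(rhs_comp)) rhs_comp[i] else NA_character_
    if (is.na(cp)) {
      if (length(in_comp) == 1L) cp <- in_comp
      else if (length(in_comp) > 1L) {
        want_surface <- graph_is_surface(prods[[i]], types)
        pick <- which(in_surface == want_surface)
        from <- stats::na.omit(vapply(reactants[pick], function(x)
          x$compartment, character(1)))
        cp <- if (length(from)) from[1L] else NA_character_
      }
    }
    prods[[i]]$compartment <- cp
  }
  prods
}

graph_is_surface <- function(g, types) {
  if (is.null(types)) return(FALSE)
  any(vapply(g$mol_type, function(t)
    !is.null(types[[t]]) && types[[t]]$dim == 2L, logical(1)))
}

#' Enumerate joint embeddings of a rule's reactant patterns into species
#'
#' @param r an `mc_rule`.
#' @param reactants list of species, one per reactant pattern (order fixed).
#' @return list of embeddings into the disjoint union of `reactants`, in the
#'   flattened pattern indexing used by [apply_rule()].
#' @export
rule_embeddings <- function(r, reactants) {
  U <- disjoint_union(reactants)
  per_pattern <- vector("list", length(r$reactants))
  for (i in seq_along(r$reactants)) {
    p <- r$reactants[[i]]
    s <- reactants[[i]]
    embs <- match_pattern(p, s)
    if (!length(embs)) return(list())
    # shift into union indexing
    moloff <- U$moloff[i]
    compoff <- if (i == 1L) 0L else length(reactants[[1L]]$comp_name)
    per_pattern[[i]] <- lapply(embs, function(e)
      list(mol = e$mol + moloff, comp = e$comp + compoff))
  }
  if (length(per_pattern) == 1L) return(per_pattern[[1L]])
  out <- list()
  for (e1 in per_pattern[[1L]]) for (e2 in per_pattern[[2L]]) {
    out[[length(out) + 1L]] <- list(mol = c(e1$mol, e2$mol),
                                    comp = c(e1$comp, e2$comp))
  }
  out
}

#' @export
print.mc_rule <- function(x, ...) {
  side <- function(gs) if (!length(gs)) "0" else
    paste(vapply(gs, complex_to_string, character(1)), collapse = " + ")
  cat("<mc_rule> ", x$name, ": ", side(x$reactants), " -> ", side(x$products),
      "  k=", format(x$rate), "\n", sep = "")
  invisible(x)
}
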