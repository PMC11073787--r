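# Graph representation of complexes: undirected bipartite graphs of elementary
# molecules and their components (binding sites with optional states).
# A fully specified, connected graph is a species; a partially specified graph
# (wildcard bonds, unset states, omitted components) is a pattern.

# Bond codes in `comp_bond`: 0 = explicitly unbound, -1 = ANY_BOND (`!?`),
# -2 = EXISTS_BOND (`!+`), k > 0 = half of bond with id k (ids local to a
# complex expression; exactly two components share an id).
BOND_NONE   <- 0L
BOND_ANY    <- -1L
BOND_EXISTS <- -2L

#' Construct a complex graph from flat component vectors
#'
#' Low-level constructor used by the parser and the rewrite engine. Most users
#' should build complexes from BNGL text with [parse_complex()].
#'
#' @param mol_type character vector of elementary molecule type names, one per
#'   molecule in the complex.
#' @param comp_mol integer vector mapping each component to the index of its
#'   owning molecule.
#' @param comp_name,comp_state character vectors of component names and states
#'   (`NA` = unset).
#' @param comp_bond integer vector of bond codes (0 unbound, -1 `!?`, -2 `!+`,
#'   positive = bond id shared by exactly two components).
#' @param stateful logical vector, whether the component type carries states
#'   (used to distinguish "unset state" from "stateless component").
#' @param compartment optional compartment name (or class `"IN"`/`"OUT"`).
#' @return an object of class `mc_complex`.
#' @export
mc_complex <- function(mol_type, comp_mol = integer(), comp_name = character(),
                       comp_state = rep(NA_character_, length(comp_name)),
                       comp_bond = rep(BOND_NONE, length(comp_name)),
                       stateful = !is.na(comp_state),
                       compartment = NA_character_) {
  g <- structure(list(
    mol_type = as.character(mol_type),
    comp_mol = as.integer(comp_mol),
    comp_name = as.character(comp_name),
    comp_state = as.character(comp_state),
    comp_bond = as.integer(comp_bond),
    stateful = as.logical(stateful),
    compartment = as.character(compartment)[1]
  ), class = "mc_complex")
  validate_complex(g)
  g
}

new_complex <- function(mol_type, comp_mol, comp_name, comp_state, comp_bond,
                        stateful, compartment = NA_character_) {
  # no-validation fast path (internal)
  structure(list(mol_type = mol_type, comp_mol = comp_mol,
                 comp_name = comp_name, comp_state = comp_state,
                 comp_bond = comp_bond, stateful = stateful,
                 compartment = compartment), class = "mc_complex")
}

validate_complex <- function(g) {
  nc <- length(g$comp_name)
  stopifnot(length(g$comp_mol) == nc, length(g$comp_state) == nc,
            length(g$comp_bond) == nc, length(g$stateful) == nc)
  if (nc && (any(g$comp_mol < 1L) || any(g$comp_mol > length(g$mol_type))))
    stop("component owner index out of range")
  ids <- g$comp_bond[g$comp_bond > 0L]
  if (length(ids)) {
    tab <- table(ids)
    if (any(tab != 2L))
      stop("every bond id must occur on exactly two components")
  }
  invisible(g)
}

n_mols <- function(g) length(g$mol_type)

# 2-column matrix of component indices joined by each bond
bond_pairs <- function(g) {
  ids <- unique(g$comp_bond[g$comp_bond > 0L])
  if (!length(ids)) return(matrix(integer(), 0L, 2L))
  t(vapply(ids, function(i) which(g$comp_bond == i), integer(2L)))
}

# partner component index for each component (NA if not bonded)
bond_partner <- function(g) {
  p <- rep(NA_integer_, length(g$comp_bond))
  bp <- bond_pairs(g)
  if (nrow(bp)) {
    p[bp[, 1L]] <- bp[, 2L]
    p[bp[, 2L]] <- bp[, 1L]
  }
  p
}

# molecule-level connected components (bonds connect molecules)
mol_components <- function(g) {
  nm <- n_mols(g)
  comp <- seq_len(nm)
  bp <- bond_pairs(g)
  if (nrow(bp)) {
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(bp))) {
        a <- g$comp_mol[bp[r, 1L]]; b <- g$comp_mol[bp[r, 2L]]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, sort(unique(comp)))
}

is_connected <- function(g) length(unique(mol_components(g))) <= 1L

#' Split a complex graph into its connected components
#'
#' Each connected component of the molecule-bond graph becomes a separate
#' `mc_complex` (bond ids are renumbered locally). Used by the rewrite engine,
#' where each connected component of a product graph is a separate product.
#'
#' @param g an `mc_complex`.
#' @return list of `mc_complex` objects.
#' @export
split_components <- function(g) {
  cc <- mol_components(g)
  lapply(sort(unique(cc)), function(k) {
    mols <- which(cc == k)
    keep <- g$comp_mol %in% mols
    bonds <- g$comp_bond[keep]
    pos <- bonds > 0L
    if (any(pos)) bonds[pos] <- match(bonds[pos], sort(unique(bonds[pos])))
    new_complex(g$mol_type[mols], match(g$comp_mol[keep], mols),
                g$comp_name[keep], g$comp_state[keep], bonds,
                g$stateful[keep], g$compartment)
  })
}

#' Test whether a complex graph is a fully specified species
#'
#' A species graph is connected, contains no bond wildcards, and every
#' stateful component has a set state.
#'
#' @param g an `mc_complex`.
#' @return logical scalar.
#' @export
is_species <- function(g) {
  if (any(g$comp_bond < 0L)) return(FALSE)
  if (any(g$stateful & is.na(g$comp_state))) return(FALSE)
  if (n_mols(g) > 1L && !is_connected(g)) return(FALSE)
  TRUE
}

## ---------------------------------------------------------------------------
## Parsing of complex expressions

# Accepts both compartment dialects: "@CP:A(...).B(...)" and "A(...).B(...)@CP".
parse_complex_tokens <- function(text) {
  txt <- gsub("[[:space:]]", "", text)
  compartment <- NA_character_
  m <- regmatches(txt, regexec("^@([A-Za-z_][A-Za-z0-9_]*):(.*)$", txt))[[1]]
  if (length(m)) { compartment <- m[2]; txt <- m[3] }
  m <- regmatches(txt, regexec("^(.*)@([A-Za-z_][A-Za-z0-9_]*)$", txt))[[1]]
  if (length(m)) {
    if (!is.na(compartment)) stop("complex '", text, "' has two compartment tags")
    compartment <- m[3]; txt <- m[2]
  }
  list(body = txt, compartment = compartment)
}

parse_molecule_token <- function(tok, multi_state = FALSE) {
  m <- regmatches(tok, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\((.*)\\))?$", tok))[[1]]
  if (!length(m)) stop("cannot parse molecule '", tok, "'")
  name <- m[2]
  comps <- list()
  if (nzchar(m[3]) && nzchar(m[4])) {
    for (ct in strsplit(m[4], ",", fixed = TRUE)[[1]]) {
      cm <- regmatches(ct, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)((~[A-Za-z0-9_]+)*)(!(\\d+|\\+|\\?))?$", ct))[[1]]
      if (!length(cm)) stop("cannot parse component '", ct, "' in '", tok, "'")
      states <- character()
      if (nzchar(cm[3]))
        states <- strsplit(sub("^~", "", cm[3]), "~", fixed = TRUE)[[1]]
      if (!multi_state && length(states) > 1L)
        stop("component '", ct, "' carries more than one state")
      bond <- BOND_NONE
      if (nzchar(cm[5])) {
        b <- cm[6]
        bond <- if (b == "+") BOND_EXISTS else if (b == "?") BOND_ANY
                else as.integer(b)
      }
      comps[[length(comps) + 1L]] <- list(name = cm[2], states = states, bond = bond)
    }
  }
  list(name = name, comps = comps)
}

#' Parse a BNGL complex expression into a graph
#'
#' Understands bonds (`!1`), bond wildcards (`!+`, `!?`), component states
#' (`~P`) and both compartment dialects (`@CP:A(...)` and `A(...)@CP`).
#' A component listed without bond syntax is explicitly unbound; omitted
#' components are unconstrained (pattern semantics).
#'
#' @param text a BNGL complex string, e.g. `"A(c0~R!1).B(c1!1)@CP"`.
#' @param types optional molecule type table (named list as produced by
#'   [parse_bngl()]); when given, component names are checked and statefulness
#'   is taken from the declaration.
#' @return an `mc_complex`.
#' @export
parse_complex <- function(text, types = NULL) {
  tk <- parse_complex_tokens(text)
  toks <- strsplit(tk$body, ".", fixed = TRUE)[[1]]
  if (!length(toks) || !nzchar(tk$body)) stop("empty complex expression '", text, "'")
  mol_type <- character(); comp_mol <- integer(); comp_name <- character()
  comp_state <- character(); comp_bond <- integer(); stateful <- logical()
  for (i in seq_along(toks)) {
    mt <- parse_molecule_token(toks[i])
    mol_type[i] <- mt$name
    decl <- if (!is.null(types)) types[[mt$name]] else NULL
    if (!is.null(types) && is.null(decl))
      stop("undeclared molecule type '", mt$name, "'")
    used <- integer()
    for (cp in mt$comps) {
      sf <- length(cp$states) > 0L
      if (!is.null(decl)) {
        slots <- setdiff(which(decl$comp_names == cp$name), used)
        if (!length(slots))
          stop("molecule type '", mt$name, "' has no free component '", cp$name, "'")
        slot <- slots[1L]; used <- c(used, slot)
        sf <- length(decl$comp_states[[slot]]) > 0L
        if (length(cp$states) && !(cp$states %in% decl$comp_states[[slot]]))
          stop("state '", cp$states, "' not allowed for ", mt$name, ".", cp$name)
      }
      comp_mol <- c(comp_mol, i)
      comp_name <- c(comp_name, cp$name)
      comp_state <- c(comp_state,
                      if (length(cp$states)) cp$states[1L] else NA_character_)
      comp_bond <- c(comp_bond, cp$bond)
      stateful <- c(stateful, sf)
    }
  }
  g <- new_complex(mol_type, comp_mol, comp_name, comp_state, comp_bond,
                   stateful, tk$compartment)
  validate_complex(g)
  g
}

#' Serialize a complex graph to BNGL text
#'
#' Molecules are written in storage order with bond ids renumbered by first
#' appearance; this is not a canonical form (see [canonical_form()]).
#'
#' @param g an `mc_complex`.
#' @param with_compartment include the `@comp` suffix if set.
#' @return single BNGL string.
#' @export
complex_to_string <- function(g, with_compartment = TRUE) {
  s <- serialize_complex(g, seq_len(n_mols(g)), comp_order_given = TRUE)
  if (with_compartment && !is.na(g$compartment))
    s <- paste0(s, "@", g$compartment)
  s
}

# Serialize with molecules in `order`. When comp_order_given, components keep
# storage order; otherwise they are sorted by the canonical component key.
serialize_complex <- function(g, order, comp_order_given = FALSE) {
  pos <- integer(n_mols(g)); pos[order] <- seq_along(order)
  partner <- bond_partner(g)
  next_id <- 0L
  bond_no <- integer(max(0L, max(c(0L, g$comp_bond))))
  out <- character(length(order))
  for (k in seq_along(order)) {
    m <- order[k]
    ci <- which(g$comp_mol == m)
    if (length(ci) > 1L && !comp_order_given) {
      key <- comp_sort_key(g, ci, pos, partner)
      ci <- ci[order(key)]
    }
    toks <- character(length(ci))
    for (j in seq_along(ci)) {
      i <- ci[j]
      t <- g$comp_name[i]
      if (!is.na(g$comp_state[i])) t <- paste0(t, "~", g$comp_state[i])
      b <- g$comp_bond[i]
      if (b == BOND_ANY) t <- paste0(t, "!?")
      else if (b == BOND_EXISTS) t <- paste0(t, "!+")
      else if (b > 0L) {
        if (bond_no[b] == 0L) { next_id <- next_id + 1L; bond_no[b] <- next_id }
        t <- paste0(t, "!", bond_no[b])
      }
      toks[j] <- t
    }
    out[k] <- paste0(g$mol_type[m],
                     if (length(toks)) paste0("(", paste(toks, collapse = ","), ")")
                     else "()")
  }
  paste(out, collapse = ".")
}

comp_sort_key <- function(g, ci, pos, partner) {
  st <- g$comp_state[ci]; st[is.na(st)] <- ""
  bcls <- ifelse(g$comp_bond[ci] > 0L, "3",
          ifelse(g$comp_bond[ci] == BOND_NONE, "0",
          ifelse(g$comp_bond[ci] == BOND_ANY, "1", "2")))
  pp <- partner[ci]
  ppos <- ifelse(is.na(pp), 0L, pos[g$comp_mol[pp]])
  pname <- ifelse(is.na(pp), "", g$comp_name[pp])
  pstate <- ifelse(is.na(pp), "", ifelse(is.na(g$comp_state[pp]), "",
                                         g$comp_state[pp]))
  sprintf("%s|%s|%s|%06d|%s|%s", g$comp_name[ci], st, bcls, ppos, pname, pstate)
}

## ---------------------------------------------------------------------------
## Canonical labeling: iterative partition refinement on
## (molecule type, component multiset, state, bond structure), then a
## deterministic adjacency-guided growth with branching over root choices;
## the lexicographically smallest serialization is the label.

#' Canonical label of a species graph
#'
#' The label is invariant under permutation of molecule storage order,
#' permutation of same-named components, and bond-id relabeling; two species
#' graphs receive equal labels iff they are isomorphic. Used as the key of the
#' network-free species cache.
#'
#' @param g an `mc_complex` that is a valid species graph.
#' @param with_compartment include the compartment tag in the label
#'   (species identity is compartment-qualified).
#' @return canonical label string.
#' @export
canonical_form <- function(g, with_compartment = TRUE) {
  if (any(g$comp_bond < 0L))
    stop("not a species: bond wildcard present")
  if (any(g$stateful & is.na(g$comp_state)))
    stop("not a species: unset component state")
  nm <- n_mols(g)
  if (nm > 1L && !is_connected(g))
    stop("not a species: graph is not connected")
  lab <- if (nm == 1L) serialize_single(g) else canonical_search(g)
  if (with_compartment && !is.na(g$compartment))
    lab <- paste0(lab, "@", g$compartment)
  lab
}

# fast path: one molecule, components sorted by (name, state); bonds impossible
# except self-loops within the molecule.
serialize_single <- function(g) {
  ci <- which(g$comp_mol == 1L)
  if (!length(ci)) return(paste0(g$mol_type[1L], "()"))
  if (any(g$comp_bond[ci] > 0L))
    return(canonical_search(g))
  st <- g$comp_state[ci]; st[is.na(st)] <- ""
  o <- order(g$comp_name[ci], st)
  toks <- ifelse(nzchar(st[o]), paste0(g$comp_name[ci][o], "~", st[o]),
                 g$comp_name[ci][o])
  paste0(g$mol_type[1L], "(", paste(toks, collapse = ","), ")")
}

refine_colors <- function(g) {
  nm <- n_mols(g); nc <- length(g$comp_name)
  partner <- bond_partner(g)
  st <- g$comp_state; st[is.na(st)] <- ""
  bcls <- ifelse(g$comp_bond > 0L, "b", "u")
  ccol <- paste(g$comp_name, st, bcls, sep = "~")
  mcol <- g$mol_type
  prev <- -1L
  repeat {
    mcol <- vapply(seq_len(nm), function(m) {
      paste(g$mol_type[m],
            paste(sort(ccol[g$comp_mol == m]), collapse = ","), sep = "|")
    }, character(1))
    mcol <- match(mcol, sort(unique(mcol)))
    pc <- ifelse(is.na(partner), 0L, match(ccol, sort(unique(ccol)))[
      ifelse(is.na(partner), 1L, partner)])
    ccol <- paste(ccol, mcol[g$comp_mol], pc, sep = "/")
    ccol <- as.character(match(ccol, sort(unique(ccol))))
    ndist <- length(unique(mcol)) + length(unique(ccol))
    if (ndist == prev) break
    prev <- ndist
  }
  list(mol = mcol, comp = ccol)
}

canonical_search <- function(g, max_serializations = 20000L) {
  nm <- n_mols(g)
  col <- refine_colors(g)
  # rank molecules by refined color, using the color's serialized content so
  # ranking is storage-order invariant
  colkey <- vapply(seq_len(nm), function(m) {
    ci <- which(g$comp_mol == m)
    st <- g$comp_state[ci]; st[is.na(st)] <- ""
    paste(g$mol_type[m], col$mol[m],
          paste(sort(paste(g$comp_name[ci], st, sep = "~")), collapse = ","),
          sep = "|")
  }, character(1))
  colrank <- match(colkey, sort(unique(colkey)))
  partner <- bond_partner(g)
  madj <- lapply(seq_len(nm), function(m) {
    ci <- which(g$comp_mol == m)
    unique(g$comp_mol[partner[ci][!is.na(partner[ci])]])
  })
  roots <- which(colrank == min(colrank))
  best <- NULL
  count <- 0L
  grow <- function(order) {
    while (length(order) < nm) {
      placed <- logical(nm); placed[order] <- TRUE
      cand <- unique(unlist(madj[order]))
      cand <- cand[!placed[cand]]
      if (!length(cand)) stop("not a species: graph is not connected")
      pos <- integer(nm); pos[order] <- seq_along(order)
      keys <- vapply(cand, function(m) {
        ci <- which(g$comp_mol == m)
        pp <- partner[ci]
        sel <- !is.na(pp) & placed[g$comp_mol[pp]]
        bonddesc <- sort(sprintf("%06d|%s|%s|%s|%s",
                                 pos[g$comp_mol[pp[sel]]],
                                 g$comp_name[pp[sel]],
                                 ifelse(is.na(g$comp_state[pp[sel]]), "",
                                        g$comp_state[pp[sel]]),
                                 g$comp_name[ci[sel]],
                                 ifelse(is.na(g$comp_state[ci[sel]]), "",
                                        g$comp_state[ci[sel]])))
        sprintf("%06d#%s", colrank[m], paste(bonddesc, collapse = ";"))
      }, character(1))
      order <- c(order, cand[which(keys == min(keys))[1L]])
    }
    order
  }
  for (r in roots) {
    count <- count + 1L
    if (count > max_serializations) stop("canonical search limit exceeded")
    s <- serialize_complex(g, grow(r))
    if (is.null(best) || s < best) best <- s
  }
  best
}

## ---------------------------------------------------------------------------

#' Enumerate the unbound state space of an elementary molecule type
#'
#' Returns the distinct canonical single-molecule species obtained by setting
#' every stateful component of the type to one of its allowed states (bonds
#' are excluded from enumeration). Duplicate-named components are deduplicated
#' canonically, so e.g. a type with two identical two-state sites yields 3
#' species, not 4.
#'
#' @param type a molecule type entry (list with `name`, `comp_names`,
#'   `comp_states`), as stored in the `molecule_types` table of a parsed model.
#' @param compartment optional compartment tag for the generated species.
#' @return list of `mc_complex` species.
#' @export
enumerate_molecule_states <- function(type, compartment = NA_character_) {
  nmc <- length(type$comp_names)
  if (!nmc) {
    return(list(new_complex(type$name, integer(), character(), character(),
                            integer(), logical(), compartment)))
  }
  statesets <- lapply(type$comp_states, function(s)
    if (length(s)) s else NA_character_)
  grid <- do.call(expand.grid, c(rev(statesets),
                                 list(KEEP.OUT.ATTRS = FALSE,
                                      stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  # canonical key: states sorted within duplicate-name groups
  groups <- split(seq_len(nmc), type$comp_names)
  keycols <- lapply(groups, function(ix) {
    if (length(ix) == 1L) return(as.character(grid[[ix]]))
    sub <- as.matrix(grid[, ix, drop = FALSE])
    apply(sub, 1L, function(r) paste(sort(r), collapse = "+"))
  })
  key <- do.call(paste, c(keycols, sep = "|"))
  keep <- which(!duplicated(key))
  stateful <- lengths(type$comp_states) > 0L
  lapply(keep, function(r) {
    new_complex(type$name, rep(1L, nmc), type$comp_names,
                as.character(unlist(grid[r, ], use.names = FALSE)),
                rep(BOND_NONE, nmc), stateful, compartment)
  })
}

#' @export
print.mc_complex <- function(x, ...) {
  cat("<mc_complex> ", complex_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.mc_complex <- function(x, ...) complex_to_string(x)
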