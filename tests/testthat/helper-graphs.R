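# Brute-force graph isomorphism oracle (independent of the canonical-label
# machinery) and a random species-graph generator for property tests.

# all type-preserving molecule bijections, with per-molecule component
# bijections preserving name and state; bonds must map onto bonds
brute_isomorphic <- function(g1, g2) {
  n <- length(g1$mol_type)
  if (n != length(g2$mol_type)) return(FALSE)
  if (length(g1$comp_name) != length(g2$comp_name)) return(FALSE)
  if (!identical(sort(g1$mol_type), sort(g2$mol_type))) return(FALSE)
  if (!identical(is.na(g1$compartment), is.na(g2$compartment)) ||
      (!is.na(g1$compartment) && g1$compartment != g2$compartment))
    return(FALSE)
  p1 <- mcreact:::bond_partner(g1)
  p2 <- mcreact:::bond_partner(g2)
  comps1 <- split(seq_along(g1$comp_mol), g1$comp_mol)
  comps2 <- split(seq_along(g2$comp_mol), g2$comp_mol)
  key <- function(g, i) paste(g$comp_name[i], g$comp_state[i])

  try_comp_maps <- function(molmap) {
    # enumerate component bijections molecule by molecule, then verify bonds
    cmap <- rep(NA_integer_, length(g1$comp_name))
    rec <- function(m) {
      if (m > n) {
        # verify bond structure
        for (i in seq_along(p1)) {
          if (is.na(p1[i])) {
            if (!is.na(p2[cmap[i]])) return(FALSE)
          } else {
            if (is.na(p2[cmap[i]]) || p2[cmap[i]] != cmap[p1[i]])
              return(FALSE)
          }
        }
        return(TRUE)
      }
      c1 <- comps1[[as.character(m)]] %||% integer()
      c2 <- comps2[[as.character(molmap[m])]] %||% integer()
      if (length(c1) != length(c2)) return(FALSE)
      assign_rec <- function(k, used) {
        if (k > length(c1)) return(rec(m + 1L))
        for (j in seq_along(c2)) {
          if (used[j]) next
          if (key(g1, c1[k]) != key(g2, c2[j])) next
          if ((g1$comp_bond[c1[k]] > 0) != (g2$comp_bond[c2[j]] > 0)) next
          cmap[c1[k]] <<- c2[j]
          used[j] <- TRUE
          if (assign_rec(k + 1L, used)) return(TRUE)
          used[j] <- FALSE
          cmap[c1[k]] <<- NA_integer_
        }
        FALSE
      }
      assign_rec(1L, logical(length(c2)))
    }
    rec(1L)
  }

  perm_rec <- function(molmap, used) {
    m <- length(molmap) + 1L
    if (m > n) return(try_comp_maps(molmap))
    for (j in seq_len(n)) {
      if (used[j] || g1$mol_type[m] != g2$mol_type[j]) next
      if (perm_rec(c(molmap, j), `[<-`(used, j, TRUE))) return(TRUE)
    }
    FALSE
  }
  perm_rec(integer(), logical(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random connected species graph over a fixed small type universe
random_species_graph <- function(n_mols = 3L) {
  repeat {
    g <- random_species_graph_once(n_mols)
    if (n_mols == 1L || mcreact:::is_connected(g)) return(g)
  }
}

random_species_graph_once <- function(n_mols = 3L) {
  types <- list(
    list(name = "A", comps = c("x", "x", "y"),
         states = list(c("u", "p"), c("u", "p"), character())),
    list(name = "B", comps = c("s", "t"),
         states = list(c("0", "1", "2"), character())),
    list(name = "C", comps = "c", states = list(character())))
  mt <- character(); cm <- integer(); cn <- character()
  cs <- character(); cb <- integer(); sf <- logical()
  for (i in seq_len(n_mols)) {
    ty <- types[[sample.int(3L, 1L)]]
    mt[i] <- ty$name
    for (k in seq_along(ty$comps)) {
      cm <- c(cm, i); cn <- c(cn, ty$comps[k])
      st <- ty$states[[k]]
      cs <- c(cs, if (length(st)) sample(st, 1L) else NA_character_)
      cb <- c(cb, 0L)
      sf <- c(sf, length(st) > 0L)
    }
  }
  # spanning-tree bonds to guarantee connectivity, plus an optional extra
  bond_id <- 0L
  for (i in seq_len(max(0L, n_mols - 1L))) {
    free_a <- which(cm %in% seq_len(i) & cb == 0L)
    free_b <- which(cm == i + 1L & cb == 0L)
    if (!length(free_a) || !length(free_b)) next
    bond_id <- bond_id + 1L
    cb[free_a[sample.int(length(free_a), 1L)]] <- bond_id
    cb[free_b[sample.int(length(free_b), 1L)]] <- bond_id
  }
  if (stats::runif(1) < 0.3) {
    free <- which(cb == 0L)
    if (length(free) >= 2L) {
      pick <- free[sample.int(length(free), 2L)]
      bond_id <- bond_id + 1L
      cb[pick] <- bond_id
    }
  }
  mcreact:::new_complex(mt, cm, cn, cs, cb, sf)
}

# random storage-order permutation of a complex (same graph, shuffled)
shuffle_graph <- function(g) {
  n <- length(g$mol_type)
  pm <- sample.int(n)     # new position of molecule i is pm[i]
  ord <- order(pm)
  idx <- unlist(lapply(ord, function(m) {
    ix <- which(g$comp_mol == m)
    ix[sample.int(length(ix))]
  }))
  bonds <- g$comp_bond[idx]
  pos <- bonds > 0L
  if (any(pos)) {
    ids <- unique(bonds[pos])
    bonds[pos] <- match(bonds[pos], sample(ids)) # relabel bond ids
  }
  mcreact:::new_complex(g$mol_type[ord], match(g$comp_mol[idx], ord),
                        g$comp_name[idx], g$comp_state[idx], bonds,
                        g$stateful[idx], g$compartment)
}
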