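# BNGL reading and writing. Supported grammar subset: optional `begin model` /
# `end model`, sections parameters / molecule types / compartments /
# seed species / observables / reaction rules, `#` comments, `\` line
# continuation. Parameter expressions support + - * / ^ and parentheses.
# BNGL functions are not supported and raise an unsupported-feature error.

## ---------------------------------------------------------------------------
## Arithmetic expression evaluator (recursive descent)

eval_bngl_expr <- function(text, env, where = "") {
  toks <- tokenize_expr(text, where)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- take()
    if (is.null(t) || t$type != type)
      stop("syntax error in expression '", text, "'", where)
    t
  }
  parse_primary <- function() {
    t <- take()
    if (is.null(t)) stop("unexpected end of expression '", text, "'", where)
    if (t$type == "num") return(t$value)
    if (t$type == "id") {
      if (!t$value %in% names(env))
        stop("undeclared identifier '", t$value, "'", where)
      return(env[[t$value]])
    }
    if (t$type == "op" && t$value == "-") return(-parse_primary())
    if (t$type == "op" && t$value == "+") return(parse_primary())
    if (t$type == "lpar") {
      v <- parse_sum()
      expect("rpar")
      return(v)
    }
    stop("syntax error in expression '", text, "'", where)
  }
  parse_pow <- function() {
    base <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "op" && t$value == "^") {
      take()
      return(base ^ parse_pow())  # right associative
    }
    base
  }
  parse_prod <- function() {
    v <- parse_pow()
    repeat {
      t <- peek()
      if (is.null(t) || t$type != "op" || !t$value %in% c("*", "/")) return(v)
      take()
      rhs <- parse_pow()
      v <- if (t$value == "*") v * rhs else v / rhs
    }
  }
  parse_sum <- function() {
    v <- parse_prod()
    repeat {
      t <- peek()
      if (is.null(t) || t$type != "op" || !t$value %in% c("+", "-")) return(v)
      take()
      rhs <- parse_prod()
      v <- if (t$value == "+") v + rhs else v - rhs
    }
  }
  v <- parse_sum()
  if (pos <= length(toks))
    stop("trailing tokens in expression '", text, "'", where)
  v
}

tokenize_expr <- function(text, where = "") {
  out <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", rest))
      out[[length(out) + 1L]] <- list(type = "num", value = as.numeric(m))
      i <- i + nchar(m); next
    }
    if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      if (substr(rest, nchar(m) + 1L, nchar(m) + 1L) == "(")
        stop("unsupported feature: function call '", m, "()' in expression",
             where, " (BNGL functions are not supported)")
      out[[length(out) + 1L]] <- list(type = "id", value = m)
      i <- i + nchar(m); next
    }
    if (ch %in% c("+", "-", "*", "/", "^")) {
      out[[length(out) + 1L]] <- list(type = "op", value = ch); i <- i + 1L; next
    }
    if (ch == "(") { out[[length(out) + 1L]] <- list(type = "lpar"); i <- i + 1L; next }
    if (ch == ")") { out[[length(out) + 1L]] <- list(type = "rpar"); i <- i + 1L; next }
    stop("syntax error: unexpected character '", ch, "'", where)
  }
  out
}

## ---------------------------------------------------------------------------
## Parser

DIFFUSION_PAR_RE <- "^MCELL_DIFFUSION_CONSTANT_(2D|3D)_([A-Za-z_][A-Za-z0-9_]*)$"

#' Parse BNGL text into a model
#'
#' Parses the supported BNGL section grammar into a fully resolved in-memory
#' model: parameter expressions are evaluated, molecule types, compartments,
#' seed species, observables and reaction rules are cross-checked against the
#' declarations, and reversible rules are split into forward/backward
#' unidirectional rules. Diffusion constants are taken from magic parameters
#' `MCELL_DIFFUSION_CONSTANT_3D_<type>` (volume) and `..._2D_<type>`
#' (surface), in cm^2/s.
#'
#' @param text BNGL source, as a single string or character vector of lines;
#'   alternatively a path to a `.bngl` file.
#' @return an object of class `bngl_model` with elements `parameters`,
#'   `molecule_types`, `compartments`, `seed_species`, `observables`,
#'   `reaction_rules`.
#' @export
parse_bngl <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  # strip comments, join continuations, keep line numbers
  lines <- sub("#.*$", "", text)
  joined <- character(); lineno <- integer()
  buf <- ""; start <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(buf)) start <- i
    if (grepl("\\\\[[:space:]]*$", ln)) {
      buf <- paste0(buf, sub("\\\\[[:space:]]*$", "", ln))
      next
    }
    full <- paste0(buf, ln); buf <- ""
    if (grepl("^[[:space:]]*$", full)) next
    joined <- c(joined, trimws(full)); lineno <- c(lineno, start)
  }
  if (nzchar(buf)) stop("line continuation at end of input")

  model <- empty_bngl_model()
  section <- NA_character_
  known <- c("parameters", "molecule types", "compartments", "seed species",
             "species", "observables", "reaction rules", "functions", "model")
  raw <- list()  # per-section raw lines
  for (k in seq_along(joined)) {
    ln <- joined[k]; at <- paste0(" (line ", lineno[k], ")")
    if (grepl("^begin\\s+", ln)) {
      sec <- trimws(sub("^begin\\s+", "", ln))
      if (!sec %in% known) stop("unknown section '", sec, "'", at)
      if (sec == "functions")
        stop("unsupported feature: BNGL functions", at)
      if (sec != "model") section <- sec
      next
    }
    if (grepl("^end\\s+", ln)) { section <- NA_character_; next }
    if (is.na(section))
      stop("syntax error: statement outside any section", at)
    raw[[section]] <- c(raw[[section]], structure(ln, names = at))
  }

  # parameters first (other sections reference them)
  env <- list()
  for (i in seq_along(raw[["parameters"]])) {
    ln <- raw[["parameters"]][[i]]
    at <- names(raw[["parameters"]])[i]
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=?\\s*(.+)$", ln))[[1]]
    if (!length(m)) stop("syntax error in parameter", at)
    env[[m[2]]] <- eval_bngl_expr(m[3], env, at)
  }
  model$parameters <- unlist(env) %||% stats::setNames(numeric(), character())

  for (i in seq_along(raw[["molecule types"]])) {
    ln <- raw[["molecule types"]][[i]]
    at <- names(raw[["molecule types"]])[i]
    mt <- parse_molecule_token(ln, multi_state = TRUE)
    dup <- split(seq_along(mt$comps), vapply(mt$comps, `[[`, "", "name"))
    for (ix in dup) {
      sts <- lapply(mt$comps[ix], `[[`, "states")
      if (length(ix) > 1L && length(unique(lapply(sts, sort))) != 1L)
        stop("duplicate components of '", mt$name,
             "' must have identical allowed states", at)
    }
    model$molecule_types[[mt$name]] <- list(
      name = mt$name,
      comp_names = vapply(mt$comps, `[[`, "", "name"),
      comp_states = lapply(mt$comps, `[[`, "states"),
      D = NA_real_, dim = 3L)
  }

  # attach diffusion constants from magic parameters
  for (p in names(model$parameters)) {
    m <- regmatches(p, regexec(DIFFUSION_PAR_RE, p))[[1]]
    if (!length(m)) next
    nm <- m[3]
    if (is.null(model$molecule_types[[nm]])) next
    model$molecule_types[[nm]]$D <- unname(model$parameters[[p]])
    model$molecule_types[[nm]]$dim <- if (m[2] == "2D") 2L else 3L
  }

  for (i in seq_along(raw[["compartments"]])) {
    ln <- raw[["compartments"]][[i]]
    at <- names(raw[["compartments"]])[i]
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3L) stop("syntax error in compartment", at)
    dim <- as.integer(f[2])
    if (!dim %in% c(2L, 3L)) stop("compartment dimension must be 2 or 3", at)
    parent <- if (length(f) >= 4L) f[4] else NA_character_
    model$compartments[[f[1]]] <- list(
      name = f[1], dim = dim,
      size = eval_bngl_expr(f[3], env, at), parent = parent)
  }
  for (cp in model$compartments) {
    if (!is.na(cp$parent)) {
      pc <- model$compartments[[cp$parent]]
      if (is.null(pc)) stop("undeclared parent compartment '", cp$parent, "'")
      if (pc$dim == cp$dim)
        stop("compartment '", cp$name,
             "' and its parent must alternate 2D/3D")
    }
  }

  seedlines <- c(raw[["seed species"]], raw[["species"]])
  for (i in seq_along(seedlines)) {
    ln <- seedlines[[i]]
    at <- names(seedlines)[i]
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.+)$", ln))[[1]]
    if (!length(m)) stop("syntax error in seed species", at)
    g <- parse_complex(m[2], model$molecule_types)
    check_compartment_ref(g, model, at)
    n <- eval_bngl_expr(m[3], env, at)
    if (n < 0 || n != round(n))
      stop("seed count must be a non-negative integer", at)
    model$seed_species[[length(model$seed_species) + 1L]] <-
      list(graph = g, count = as.integer(round(n)))
  }

  for (i in seq_along(raw[["observables"]])) {
    ln <- raw[["observables"]][[i]]
    at <- names(raw[["observables"]])[i]
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3L) stop("syntax error in observable", at)
    kind <- f[1]
    if (!kind %in% c("Molecules", "Species"))
      stop("observable kind must be Molecules or Species", at)
    pats <- lapply(f[-(1:2)], parse_complex, types = model$molecule_types)
    for (p in pats) check_compartment_ref(p, model, at)
    model$observables[[length(model$observables) + 1L]] <-
      list(kind = kind, name = f[2], patterns = pats)
  }

  for (i in seq_along(raw[["reaction rules"]])) {
    ln <- raw[["reaction rules"]][[i]]
    at <- names(raw[["reaction rules"]])[i]
    for (r in parse_rule_line(ln, model, env, at))
      model$reaction_rules[[length(model$reaction_rules) + 1L]] <- r
  }
  names(model$reaction_rules) <-
    vapply(model$reaction_rules, `[[`, "", "name")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_bngl_model <- function() {
  structure(list(parameters = stats::setNames(numeric(), character()),
                 molecule_types = list(), compartments = list(),
                 seed_species = list(), observables = list(),
                 reaction_rules = list()),
            class = "bngl_model")
}

check_compartment_ref <- function(g, model, at = "") {
  cp <- g$compartment
  if (is.na(cp) || cp %in% c("IN", "OUT")) return(invisible())
  if (length(model$compartments) && is.null(model$compartments[[cp]]))
    stop("undeclared compartment '", cp, "'", at)
  invisible()
}

# One rule line -> one or two (reversible split) unidirectional mc_rule
parse_rule_line <- function(ln, model, env, at = "") {
  name <- NA_character_
  m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*):\\s*(.*)$", ln))[[1]]
  if (length(m)) { name <- m[2]; ln <- m[3] }
  rev <- grepl("<->", ln, fixed = TRUE)
  sides <- strsplit(ln, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("syntax error in reaction rule", at)
  rhs <- trimws(sides[2])
  mm <- regmatches(rhs, regexec("^(\\S+(?:\\s*\\+\\s*\\S+)*)\\s+(\\S.*)$", rhs))[[1]]
  if (!length(mm)) stop("missing rate in reaction rule", at)
  prodtxt <- mm[2]; ratetxt <- mm[3]
  rates <- vapply(strsplit(ratetxt, ",", fixed = TRUE)[[1]],
                  function(e) eval_bngl_expr(trimws(e), env, at), 0)
  if (rev && length(rates) != 2L)
    stop("reversible rule needs two rates", at)
  if (!rev && length(rates) != 1L)
    stop("irreversible rule needs one rate", at)
  parse_side <- function(s) {
    # reactant separator is a '+' with surrounding whitespace (a bare '+'
    # can occur inside a bond wildcard '!+')
    toks <- trimws(strsplit(paste0(" ", s, " "), "\\s\\+\\s")[[1]])
    toks <- toks[nzchar(toks)]
    if (identical(toks, "0")) return(list())
    lapply(toks, function(t) {
      g <- parse_complex(t, model$molecule_types)
      check_compartment_ref(g, model, at)
      g
    })
  }
  lhs <- parse_side(sides[1]); prods <- parse_side(prodtxt)
  if (!length(lhs)) stop("rule needs at least one reactant", at)
  if (length(lhs) > 2L)
    stop("at most two reactant patterns are supported", at)
  if (is.na(name)) name <- paste0("rule", length(model$reaction_rules) + 1L)
  fwd <- mc_rule(name, lhs, prods, rates[[1]])
  if (!rev) return(list(fwd))
  if (length(prods) > 2L)
    stop("reverse of rule with >2 products is not a valid rule", at)
  list(fwd, mc_rule(paste0(name, "_rev"), prods, lhs, rates[[2]]))
}

## ---------------------------------------------------------------------------
## Writer

#' Write a model back to BNGL text
#'
#' Produces BNGL that re-parses to a model with identical canonical content.
#' When given a spatial model bundle, spatial-only features (meshes, mesh
#' releases, surface classes, callbacks) cannot be represented in BNGL; they
#' are listed in the `warnings` attribute of the result rather than silently
#' dropped.
#'
#' @param m a `bngl_model` (or a spatial `mc_model_bundle`, whose BNGL part is
#'   exported best-effort).
#' @param path optional file to write to.
#' @return invisibly, the BNGL text (single string) with attribute
#'   `warnings` (character vector of untranslatable features).
#' @export
write_bngl <- function(m, path = NULL) {
  warnings <- character()
  if (inherits(m, "mc_model_bundle")) {
    warnings <- spatial_export_warnings(m)
    m <- m$bngl
  }
  stopifnot(inherits(m, "bngl_model"))
  out <- c("begin model")
  if (length(m$parameters)) {
    out <- c(out, "begin parameters",
             sprintf("  %s %.17g", names(m$parameters), m$parameters),
             "end parameters")
  }
  if (length(m$molecule_types)) {
    out <- c(out, "begin molecule types",
             vapply(m$molecule_types, function(t) {
               comps <- mapply(function(n, s)
                 paste0(n, paste0(rep("~", length(s)), s, collapse = "")),
                 t$comp_names, t$comp_states)
               paste0("  ", t$name, "(", paste(comps, collapse = ","), ")")
             }, character(1)),
             "end molecule types")
  }
  if (length(m$compartments)) {
    out <- c(out, "begin compartments",
             vapply(m$compartments, function(cp)
               trimws(sprintf("  %s %d %.17g %s", cp$name, cp$dim, cp$size,
                              if (is.na(cp$parent)) "" else cp$parent),
                      which = "right"),
               character(1)),
             "end compartments")
  }
  if (length(m$seed_species)) {
    out <- c(out, "begin seed species",
             vapply(m$seed_species, function(s)
               sprintf("  %s %d", complex_to_string(s$graph), s$count),
               character(1)),
             "end seed species")
  }
  if (length(m$observables)) {
    out <- c(out, "begin observables",
             vapply(m$observables, function(o)
               paste("  ", o$kind, o$name,
                     paste(vapply(o$patterns, complex_to_string, character(1)),
                           collapse = " ")),
               character(1)),
             "end observables")
  }
  if (length(m$reaction_rules)) {
    out <- c(out, "begin reaction rules",
             vapply(m$reaction_rules, function(r) {
               side <- function(gs) if (!length(gs)) "0" else
                 paste(vapply(gs, complex_to_string, character(1)),
                       collapse = " + ")
               sprintf("  %s: %s -> %s %.17g", r$name, side(r$reactants),
                       side(r$products), r$rate)
             }, character(1)),
             "end reaction rules")
  }
  out <- c(out, "end model")
  text <- paste(out, collapse = "\n")
  attr(text, "warnings") <- warnings
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}

spatial_export_warnings <- function(bundle) {
  w <- character()
  for (go in bundle$geometry) {
    w <- c(w, paste0("geometry object '", go$name,
                     "' has no BNGL equivalent (mesh exported as compartment volume only)"))
  }
  for (rs in bundle$releases) {
    if (!is.null(rs$shape) && rs$shape %in% c("surface_region", "points"))
      w <- c(w, paste0("release of '", rs$species,
                       "' at a spatial location cannot be expressed in BNGL"))
  }
  if (length(bundle$surface_classes))
    w <- c(w, "species-selective surface classes cannot be expressed in BNGL")
  if (length(bundle$callbacks))
    w <- c(w, "event callbacks cannot be expressed in BNGL")
  w
}

#' @export
print.bngl_model <- function(x, ...) {
  cat("<bngl_model>",
      length(x$molecule_types), "molecule types,",
      length(x$compartments), "compartments,",
      length(x$seed_species), "seed species,",
      length(x$observables), "observables,",
      length(x$reaction_rules), "reaction rules\n")
  invisible(x)
}
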