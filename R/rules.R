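# Rule-level utilities: compartment-class resolution, derived diffusion
# constants for complexes, and rate-unit conversion between the simulator's
# default unit system and BNG-style units.

AVOGADRO <- 6.02214076e23

#' Resolve @IN/@OUT compartment classes on a rule
#'
#' The classes @IN and @OUT may appear only on the volume reactant (and
#' volume products) of a bimolecular rule in which one volume and one surface
#' molecule interact. Given the membrane compartment that holds the surface
#' reactant, @OUT resolves to the 3D compartment outside that membrane (its
#' parent) and @IN to the 3D compartment inside it (its 3D child).
#'
#' @param r an `mc_rule` possibly carrying `IN`/`OUT` compartment tags.
#' @param surface_compartment name of the 2D compartment holding the surface
#'   reactant at resolution time.
#' @param compartments compartment table (named list with `dim`, `parent`).
#' @param types molecule type table, used to verify the volume+surface shape
#'   of the rule.
#' @return a concrete `mc_rule` with all class tags replaced; the rule is
#'   returned unchanged if it uses no classes.
#' @export
resolve_compartment_classes <- function(r, surface_compartment = NULL,
                                        compartments = list(), types = NULL) {
  tags <- c(vapply(r$reactants, function(g) g$compartment, character(1)),
            vapply(r$products, function(g) g$compartment, character(1)))
  if (!any(tags %in% c("IN", "OUT"), na.rm = TRUE)) return(r)
  if (length(r$reactants) != 2L)
    stop("@IN/@OUT require a bimolecular volume+surface rule")
  surf <- vapply(r$reactants, graph_is_surface, logical(1), types = types)
  if (sum(surf) != 1L)
    stop("@IN/@OUT require exactly one volume and one surface reactant")
  if (any(vapply(r$reactants[surf], function(g)
    isTRUE(g$compartment %in% c("IN", "OUT")), logical(1))))
    stop("@IN/@OUT may tag only the volume reactant")
  if (is.null(surface_compartment))
    stop("surface compartment required to resolve @IN/@OUT")
  mem <- compartments[[surface_compartment]]
  if (is.null(mem) || mem$dim != 2L)
    stop("'", surface_compartment, "' is not a declared membrane compartment")
  outer <- mem$parent
  if (is.na(outer) || is.null(compartments[[outer]]))
    stop("membrane '", surface_compartment, "' has no outer compartment")
  inner <- names(compartments)[vapply(compartments, function(cp)
    identical(cp$parent, surface_compartment), logical(1))]
  if (!length(inner))
    stop("membrane '", surface_compartment, "' has no inner compartment")
  inner <- inner[1L]
  subst <- function(g) {
    if (isTRUE(g$compartment == "IN")) g$compartment <- inner
    else if (isTRUE(g$compartment == "OUT")) g$compartment <- outer
    else if (is.na(g$compartment) && graph_is_surface(g, types))
      g$compartment <- surface_compartment
    g
  }
  mc_rule(r$name, lapply(r$reactants, subst), lapply(r$products, subst),
          r$rate)
}

#' Derive the diffusion constant and surface/volume class of a complex
#'
#' A complex containing any subunit with a zero diffusion constant is
#' immobile. A complex containing any surface subunit is a surface complex
#' and only the surface subunits enter the surface combining rule
#' D = (sum Di^-2)^(-1/2) (areas additive). A pure volume complex uses
#' D = (sum Di^-3)^(-1/3) (effective radii ri proportional to 1/Di, volumes
#' additive); a homodimer therefore diffuses at D0 * 2^(-1/3).
#'
#' @param g an `mc_complex` species.
#' @param types molecule type table with per-type `D` (cm^2/s) and `dim`.
#' @return list with `D` (cm^2/s) and `dim` (2 for a surface complex, 3 for a
#'   volume complex).
#' @export
derive_diffusion_constant <- function(g, types) {
  Ds <- vapply(g$mol_type, function(t) {
    ty <- types[[t]]
    if (is.null(ty)) stop("undeclared molecule type '", t, "'")
    if (is.na(ty$D)) stop("molecule type '", t, "' has no diffusion constant")
    ty$D
  }, 0)
  dims <- vapply(g$mol_type, function(t) types[[t]]$dim, 0L)
  surface <- any(dims == 2L)
  if (any(Ds == 0)) return(list(D = 0, dim = if (surface) 2L else 3L))
  if (surface) {
    Dsurf <- Ds[dims == 2L]
    list(D = sum(Dsurf^-2)^(-1 / 2), dim = 2L)
  } else {
    list(D = sum(Ds^-3)^(-1 / 3), dim = 3L)
  }
}

#' Convert a rate constant between unit systems
#'
#' The simulator's default unit system uses: volume-volume
#' and volume-surface bimolecular rates in M^-1 s^-1, surface-surface rates
#' in um^2 N^-1 s^-1, unimolecular rates in s^-1. BNG-style units use
#' um^3 N^-1 s^-1 for all bimolecular rates, interpreting a membrane as a
#' thin volume of thickness 0.01 um.
#'
#' @param k rate constant in the `from` system.
#' @param context one of `"vol_bimol"` (volume-volume or volume-surface),
#'   `"surf_bimol"` (surface-surface), `"unimol"`.
#' @param from,to unit system, `"mcell"` or `"bng"`.
#' @param membrane_thickness membrane thickness in um (default 0.01).
#' @return converted rate constant.
#' @export
convert_rate_units <- function(k, context, from = "mcell", to = "bng",
                               membrane_thickness = 0.01) {
  stopifnot(from %in% c("mcell", "bng"), to %in% c("mcell", "bng"))
  if (from == to) return(k)
  per_M_to_um3 <- 1e15 / AVOGADRO  # 1 M^-1 s^-1 in um^3 N^-1 s^-1
  switch(context,
    unimol = k,
    vol_bimol = if (from == "mcell") k * per_M_to_um3 else k / per_M_to_um3,
    surf_bimol = if (from == "mcell") k * membrane_thickness
                 else k / membrane_thickness,
    stop("unknown reaction context '", context, "'"))
}

# Classify a rule's reaction context from its reactant patterns.
rule_context <- function(r, types) {
  if (length(r$reactants) == 1L) return("unimol")
  surf <- vapply(r$reactants, graph_is_surface, logical(1), types = types)
  if (all(surf)) "surf_bimol" else "vol_bimol"
}
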