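# Built-in fixture models. Each fixture returns a ready model bundle; the
# defaults reproduce the documented study conditions and the `...` overrides
# support the desk-scale variants used by the test suite (sizes stated in
# the methods vignette). Rate constants for the membrane-localization,
# autophosphorylation and clock fixtures are synthetic values reconstructed
# from the published model family they implement.

#' Built-in fixture models
#'
#' @param name one of `"wellmixed_abc"`, `"snare"`,
#'   `"membrane_localization"`, `"autophosphorylation"`, `"psd_spine"`,
#'   `"clock_particle"`, `"clock_hybrid"`.
#' @param seed RNG seed for the fixture's configuration.
#' @param ... fixture-specific overrides, see the individual builder
#'   functions (`fixture_clock()`, `fixture_membrane()`, ...).
#' @return an `mc_model_bundle`.
#' @export
fixture_model <- function(name, seed = 1, ...) {
  switch(name,
    wellmixed_abc = fixture_wellmixed_abc(seed, ...),
    snare = fixture_snare(seed, ...),
    membrane_localization = fixture_membrane(seed, ...),
    autophosphorylation = fixture_autophos(seed, ...),
    psd_spine = fixture_psd_spine(seed, ...),
    clock_particle = fixture_clock(seed, hybrid = FALSE, ...),
    clock_hybrid = fixture_clock(seed, hybrid = TRUE, ...),
    stop("unknown fixture '", name, "'"))
}

fixture_wellmixed_abc <- function(seed, count_stride = 100L, dt = 1e-6) {
  load_bngl_into_model(
    system.file("extdata", "abc.bngl", package = "mcreact"),
    config = simulation_config(dt = dt, seed = seed,
                               count_stride = count_stride))
}

fixture_snare <- function(seed, count_stride = 100L, dt = 1e-6) {
  load_bngl_into_model(
    system.file("extdata", "snare.bngl", package = "mcreact"),
    config = simulation_config(dt = dt, seed = seed,
                               count_stride = count_stride))
}

#' Membrane localization fixture
#'
#' Volume proteins A and B bind a membrane lipid M (initial density 17000
#' molecules/um^2 on one small face of a 0.47 x 0.47 x 5 um^3 box, surface
#' grid density 40000 tiles/um^2, i.e. 42.5% initial occupancy) and the
#' membrane-bound forms MA and MB dimerize in 2D. The face's four edges are
#' reflective to 2D diffusion. Overridable face/length/counts support a
#' reduced test-scale variant.
#'
#' @param seed RNG seed.
#' @param face face edge length (um).
#' @param length box length perpendicular to the face (um).
#' @param n_A,n_B volume molecule counts.
#' @param density_M surface density of M (N/um^2).
#' @param grid_density surface grid density (tiles/um^2).
#' @param count_stride,dt output cadence and time step.
#' @return an `mc_model_bundle`.
#' @export
fixture_membrane <- function(seed, face = 0.47, length = 5, n_A = 1000,
                             n_B = 1000, density_M = 17000,
                             grid_density = 40000,
                             count_stride = 1000L, dt = 1e-6) {
  V <- face * face * length
  area <- 6 * face * length + 2 * face^2  # full box area (declared 2D size)
  txt <- c(
    "begin model", "begin parameters",
    "MCELL_DIFFUSION_CONSTANT_3D_A 1e-6",
    "MCELL_DIFFUSION_CONSTANT_3D_B 1e-6",
    "MCELL_DIFFUSION_CONSTANT_2D_M 1e-8",
    "MCELL_DIFFUSION_CONSTANT_2D_MA 1e-8",
    "MCELL_DIFFUSION_CONSTANT_2D_MB 1e-8",
    "MCELL_DIFFUSION_CONSTANT_2D_MAMB 1e-8",
    "ka_on 5e7", "ka_off 10",      # volume-surface binding, M^-1 s^-1 / s^-1
    "k2_on 0.2", "k2_off 1",       # surface-surface, um^2 N^-1 s^-1 / s^-1
    "end parameters",
    "begin molecule types",
    "A(m)", "B(m)", "M(s)", "MA(d)", "MB(d)", "MAMB()",
    "end molecule types",
    "begin compartments",
    sprintf("PM 2 %.9g", area),
    sprintf("CP 3 %.9g PM", V),
    "end compartments",
    "begin seed species", "end seed species",
    "begin observables",
    "Molecules MA MA(d) MAMB()",
    "Molecules MB MB(d) MAMB()",
    "Molecules MAMB MAMB()",
    "Molecules M_free M(s)",
    "end observables",
    "begin reaction rules",
    "bindA: A(m) + M(s) <-> MA(d) ka_on, ka_off",
    "bindB: B(m) + M(s) <-> MB(d) ka_on, ka_off",
    "dimer: MA(d) + MB(d) <-> MAMB() k2_on, k2_off",
    "end reaction rules", "end model")
  m <- parse_bngl(txt)
  # geometry: box with a named region "cap" (the z- face) carrying M;
  # the cap's edges reflect 2D diffusion
  mesh <- make_box(c(0, 0, length / 2), c(face, face, length))
  regions <- list(cap = c(1L, 2L))  # the two z- triangles of make_box
  go <- geometry_object(mesh, "cell", inside_compartment = "CP",
                        surface_compartment = "PM", regions = regions,
                        region_edges_reflective = "cap")
  rel <- list(
    release_site("M(s)@PM", shape = "surface", density = density_M,
                 object = "cell", region = "cap"),
    release_site("A(m)@CP", shape = "volume", count = n_A, object = "cell"),
    release_site("B(m)@CP", shape = "volume", count = n_B, object = "cell"))
  model_bundle(m, geometry = list(go), releases = rel,
               config = simulation_config(dt = dt, seed = seed,
                                          grid_density = grid_density,
                                          count_stride = count_stride))
}

#' Kinase autophosphorylation fixture (bistable switch)
#'
#' A kinase K phosphorylates itself in trans (K~0 + K~1 -> 2 K~1) with a
#' weak basal rate, and a single saturable phosphatase P dephosphorylates
#' via an explicit enzyme-substrate complex. The deterministic system is
#' bistable; stochastic trajectories switch between the two ODE steady
#' states.
#'
#' @param seed RNG seed.
#' @param n_K,n_P copy numbers (default 30 kinases, 1 phosphatase).
#' @param volume box volume in um^3.
#' @param count_stride,dt output cadence and time step.
#' @return an `mc_model_bundle`.
#' @export
fixture_autophos <- function(seed, n_K = 30, n_P = 1, volume = 0.0078,
                             count_stride = 1000L, dt = 1e-6) {
  txt <- c(
    "begin model", "begin parameters",
    "MCELL_DIFFUSION_CONSTANT_3D_K 1e-6",
    "MCELL_DIFFUSION_CONSTANT_3D_P 1e-6",
    "k_auto 1.1e7",   # M^-1 s^-1 trans-autophosphorylation
    "k_basal 2",      # s^-1
    "k_on 1e9", "k_off 100", "k_cat 500",
    sprintf("N_K %d", n_K), sprintf("N_P %d", n_P),
    "end parameters",
    "begin molecule types", "K(p~0~1,b)", "P(b)", "end molecule types",
    "begin compartments", sprintf("CP 3 %.9g", volume), "end compartments",
    "begin seed species",
    "@CP:K(p~0,b) N_K", "@CP:P(b) N_P",
    "end seed species",
    "begin observables",
    "Molecules Kp K(p~1)",
    "Molecules Ku K(p~0)",
    "end observables",
    "begin reaction rules",
    "auto: K(p~0) + K(p~1) -> K(p~1) + K(p~1) k_auto",
    "basal: K(p~0) -> K(p~1) k_basal",
    "bind: K(p~1,b) + P(b) <-> K(p~1,b!1).P(b!1) k_on, k_off",
    "cat: K(p~1,b!1).P(b!1) -> K(p~0,b) + P(b) k_cat",
    "end reaction rules", "end model")
  load_bngl_into_model(txt, config = simulation_config(
    dt = dt, seed = seed, count_stride = count_stride))
}

#' Dendritic-spine fixture with a species-selective subcompartment
#'
#' A 0.5 um spine-head box contains a 0.05 x 0.4 x 0.4 um subcompartment
#' (the postsynaptic density) whose walls are reflective to the kinase and
#' its scaffold partner but transparent to calcium: a reduced-species
#' variant of a spine with a PSD, exercising species-selective surface
#' classes and a structurally combinatorial holoenzyme type that is never
#' network-expanded.
#'
#' @param seed RNG seed.
#' @param n_kinase,n_ca copy numbers.
#' @param count_stride,dt output cadence and time step.
#' @return an `mc_model_bundle`.
#' @export
fixture_psd_spine <- function(seed, n_kinase = 50, n_ca = 200,
                              count_stride = 100L, dt = 1e-6) {
  txt <- c(
    "begin model", "begin parameters",
    "MCELL_DIFFUSION_CONSTANT_3D_CaM 1e-6",
    "MCELL_DIFFUSION_CONSTANT_3D_Ca 2e-6",
    "k_bind 5e8", "k_unbind 50",
    "end parameters",
    "begin molecule types",
    "CaM(c~0~1~2)", "Ca()",
    "end molecule types",
    "begin compartments", "SP 3 0.125", "end compartments",
    "begin seed species", "end seed species",
    "begin observables",
    "Molecules Ca_free Ca()",
    "Molecules CaM_loaded CaM(c~2)",
    "end observables",
    "begin reaction rules",
    "b1: CaM(c~0) + Ca() <-> CaM(c~1) k_bind, k_unbind",
    "b2: CaM(c~1) + Ca() <-> CaM(c~2) k_bind, k_unbind",
    "end reaction rules", "end model")
  m <- parse_bngl(txt)
  spine <- geometry_object(make_box(c(0, 0, 0), c(0.5, 0.5, 0.5)),
                           "spine", inside_compartment = "SP")
  psd <- geometry_object(make_box(c(0.2, 0, 0), c(0.05, 0.4, 0.4)), "psd")
  rel <- list(
    release_site("CaM(c~0)@SP", shape = "volume", count = n_kinase,
                 object = "spine"),
    release_site("Ca()@SP", shape = "volume", count = n_ca,
                 object = "spine"))
  sc <- list(
    list(species = "Ca", object = "psd", behavior = "transparent"),
    list(species = "CaM", object = "psd", behavior = "reflective"))
  model_bundle(m, geometry = list(spine, psd), releases = rel,
               surface_classes = sc,
               config = simulation_config(dt = dt, seed = seed,
                                          count_stride = count_stride))
}

#' Activator-repressor circadian clock fixture
#'
#' The two-gene relaxation oscillator: activator A enhances transcription of
#' both its own gene and the repressor gene; R sequesters A into a complex C
#' whose decay releases R. Rates follow the published oscillator with all
#' rates carried from hours to seconds and the volume reduced to a 0.25 um
#' box; `volume_scale` applies a further exact concentration-preserving
#' reduction (volume and transcription divided by the same factor) to reach
#' desk-scale copy numbers.
#'
#' In the hybrid variant R is a continuous copy number updated by an
#' explicit Euler step each iteration, the bimolecular A + R -> C becomes
#' the pseudo-first-order rule `A_to_C` whose rate tracks gC/V * R(t), and
#' C decay feeds R back (+1 per firing).
#'
#' @param seed RNG seed.
#' @param hybrid simulate R as a continuous species.
#' @param D diffusion constant of all mobile species (cm^2/s); the genes
#'   are immobile.
#' @param volume_scale exact concentration-preserving reduction factor.
#' @param dt time step; defaults to 1e-6 (particle) or 2e-6 (hybrid, where
#'   the fast R reactions need not be resolved).
#' @param rint_factor multiplier on the default interaction radius (the
#'   slow-diffusion variant uses 2 to keep reaction probabilities below 1).
#' @param count_stride output cadence.
#' @return an `mc_model_bundle`.
#' @export
fixture_clock <- function(seed, hybrid = FALSE, D = 1e-5, volume_scale = 1,
                          dt = if (hybrid) 2e-6 else 1e-6,
                          rint_factor = 1, count_stride = 100L) {
  V0 <- 268 * 0.015625           # pre-reduction volume, um^3
  V <- 0.015625 / volume_scale
  acc <- 268                     # unimolecular acceleration
  k3 <- function(g) g * V0       # bimolecular (per mol per s) -> um^3/N/s
  p <- list(
    aA = 50 * acc / volume_scale, aAp = 500 * acc / volume_scale,
    aR = 0.01 * acc / volume_scale, aRp = 50 * acc / volume_scale,
    bA = 50 * acc, bR = 5 * acc,
    dMA = 10 * acc, dMR = 0.5 * acc,
    dA = 1 * acc, dR = 0.2 * acc,
    gA = k3(1), gR = k3(1), gC = k3(2),
    tA = 50 * acc, tR = 100 * acc)
  head <- c(
    "begin model", "begin parameters",
    "MCELL_DIFFUSION_CONSTANT_3D_Da 0",
    "MCELL_DIFFUSION_CONSTANT_3D_Dr 0",
    sprintf("MCELL_DIFFUSION_CONSTANT_3D_Ma %g", D),
    sprintf("MCELL_DIFFUSION_CONSTANT_3D_Mr %g", D),
    sprintf("MCELL_DIFFUSION_CONSTANT_3D_A %g", D),
    sprintf("MCELL_DIFFUSION_CONSTANT_3D_R %g", D),
    sprintf("MCELL_DIFFUSION_CONSTANT_3D_C %g", D),
    sprintf("aA %.9g", p$aA), sprintf("aAp %.9g", p$aAp),
    sprintf("aR %.9g", p$aR), sprintf("aRp %.9g", p$aRp),
    sprintf("bA %.9g", p$bA), sprintf("bR %.9g", p$bR),
    sprintf("dMA %.9g", p$dMA), sprintf("dMR %.9g", p$dMR),
    sprintf("dA %.9g", p$dA), sprintf("dR %.9g", p$dR),
    sprintf("gA %.9g", p$gA), sprintf("gR %.9g", p$gR),
    sprintf("gC %.9g", p$gC),
    sprintf("tA %.9g", p$tA), sprintf("tR %.9g", p$tR),
    "end parameters",
    "begin molecule types",
    "Da(b)", "Dr(b)", "Ma()", "Mr()", "A(b)", "R()", "C()",
    "end molecule types",
    "begin compartments", sprintf("CP 3 %.9g", V), "end compartments",
    "begin seed species", "@CP:Da(b) 1", "@CP:Dr(b) 1", "end seed species",
    "begin observables",
    "Molecules A_free A(b)",
    "Molecules C_cplx C()",
    if (!hybrid) "Molecules R_free R()",
    "end observables")
  common_rules <- c(
    "actA: Da(b) + A(b) <-> Da(b!1).A(b!1) gA, tA",
    "txA0: Da(b) -> Da(b) + Ma() aA",
    "txA1: Da(b!+) -> Da(b!+) + Ma() aAp",
    "tlA: Ma() -> Ma() + A(b) bA",
    "degMa: Ma() -> 0 dMA",
    "degA: A(b) -> 0 dA",
    "actR: Dr(b) + A(b) <-> Dr(b!1).A(b!1) gR, tR",
    "txR0: Dr(b) -> Dr(b) + Mr() aR",
    "txR1: Dr(b!+) -> Dr(b!+) + Mr() aRp",
    "degMr: Mr() -> 0 dMR")
  if (!hybrid) {
    rules <- c(common_rules,
      "tlR: Mr() -> Mr() + R() bR",
      "degR: R() -> 0 dR",
      "seq: A(b) + R() -> C() gC",
      "relR: C() -> R() dA")
  } else {
    rules <- c(common_rules,
      "A_to_C: A(b) -> C() 0",    # pseudo-first-order, rate = gC/V * R(t)
      "relR: C() -> 0 dA")        # R release handled by the hybrid update
  }
  txt <- c(head, "begin reaction rules", rules,
           "end reaction rules", "end model")
  txt <- txt[!vapply(txt, is.null, logical(1))]
  m <- parse_bngl(txt)
  cfg <- simulation_config(
    dt = dt, seed = seed, count_stride = count_stride, units = "bng",
    interaction_radius = rint_factor / sqrt(pi * 1e4))
  hyb <- NULL
  if (hybrid) {
    hyb <- hybrid_species(
      name = "R_free", value0 = 0, decay = p$dR,
      prod = stats::setNames(p$bR, "Mr()@CP"),
      cons = stats::setNames(p$gC / V, "A(b)@CP"),
      gain_rules = "relR",
      coupled_rule = "A_to_C", coupled_coef = p$gC / V)
  }
  bundle <- load_bngl_into_model(txt, config = cfg)
  bundle$hybrid <- hyb
  bundle
}

#' Expanded network of the particle clock (for the SSA/ODE oracles)
#'
#' @param volume_scale concentration-preserving reduction factor (match the
#'   fixture).
#' @return list with the `mc_network`, initial counts `y0`, the volume, and
#'   unit system.
#' @export
clock_network <- function(volume_scale = 1) {
  b <- fixture_clock(1, hybrid = FALSE, volume_scale = volume_scale)
  net <- expand_network(b$bngl)
  y0 <- stats::setNames(c(1, 1), c("Da(b)@CP", "Dr(b)@CP"))
  list(net = net, y0 = y0, volume = 0.015625 / volume_scale, units = "bng")
}
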