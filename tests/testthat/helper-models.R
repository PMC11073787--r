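# Small programmatic model builders shared by the engine tests.

# open-space world: molecules of one species released at given points,
# no geometry, no chemistry
open_world <- function(n, D = 1e-6, seed = 1, dt = 1e-6, stride = 1000L) {
  txt <- c("begin parameters",
           sprintf("MCELL_DIFFUSION_CONSTANT_3D_a %g", D),
           "end parameters",
           "begin molecule types", "a()", "end molecule types",
           "begin observables", "Molecules a a()", "end observables")
  b <- model_bundle(parse_bngl(txt),
                    releases = list(release_site(
                      "a()", shape = "points",
                      points = matrix(0, n, 3))),
                    config = simulation_config(dt = dt, seed = seed,
                                               count_stride = stride))
  build_world(b)
}

# one-species box world with optional extra BNGL lines
box_world <- function(side = 1, n = 100, D = 1e-5, seed = 1, dt = 1e-6,
                      stride = 1000L, extra_types = character(),
                      extra_params = character(), rules = character(),
                      extra_seeds = character(), obs = character()) {
  txt <- c("begin model", "begin parameters",
           sprintf("MCELL_DIFFUSION_CONSTANT_3D_a %g", D),
           extra_params, "end parameters",
           "begin molecule types", "a()", extra_types,
           "end molecule types",
           "begin compartments", sprintf("CP 3 %.12g", side^3),
           "end compartments",
           "begin seed species", sprintf("@CP:a() %d", n), extra_seeds,
           "end seed species",
           "begin observables", "Molecules a a()", obs, "end observables",
           "begin reaction rules", rules, "end reaction rules", "end model")
  build_world(load_bngl_into_model(txt, config = simulation_config(
    dt = dt, seed = seed, count_stride = stride)))
}
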