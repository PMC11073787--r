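# Monte Carlo core: displacement sampling, collision probabilities,
# scheduler order, releases, unimolecular kinetics, reflection, exclusion,
# and determinism.

test_that("displacement sampling has the Brownian moments", {
  set.seed(1)
  D <- 1e-6; dt <- 1e-6
  d3 <- sample_displacement(D, dt, n = 1e5, dim = 3L)
  msd <- rowSums(d3^2)
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - 6 * D * 1e8 * dt), 3 * se)
  # mean step length: Maxwell distribution moment sqrt(16 D dt / pi)
  len <- sqrt(msd)
  se2 <- stats::sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - sqrt(16 * D * 1e8 * dt / pi)), 3 * se2)
  expect_equal(sample_displacement(0, dt, n = 3L), matrix(0, 3, 3))
})

test_that("collision probability formulas match hand evaluation", {
  expect_equal(reaction_probability_vv(0, 1e-6, 1e-6, 0.005, 1e-6), 0)
  k <- 1.66054; D <- 1e-5; r <- 1 / sqrt(pi * 1e4); dt <- 1e-6
  lbar <- sqrt(16 * D * 1e8 * dt / pi)
  expect_equal(reaction_probability_vv(k, D, D, r, dt),
               k * dt / (pi * r^2 * (2 * lbar)))
  expect_equal(reaction_probability_vs(0, D, 1e-4, dt), 0)
  expect_equal(reaction_probability_vs(0.5, D, 1e-4, dt),
               0.5 * dt / (1e-4 * sqrt(D * 1e8 * dt / pi)))
  # the engine reports the same probability it was asked to use
  w <- box_world(side = 1, n = 100, D = 1e-5, seed = 2,
                 extra_types = c("b()", "c()"),
                 extra_params = c("MCELL_DIFFUSION_CONSTANT_3D_b 1e-5",
                                  "MCELL_DIFFUSION_CONSTANT_3D_c 1e-5",
                                  "kk 1e9"),
                 extra_seeds = "@CP:b() 100",
                 rules = "fwd: a() + b() -> c() kk")
  run_iterations(w, 300)
  p_expect <- reaction_probability_vv(convert_rate_units(1e9, "vol_bimol",
                                                         "mcell", "bng"),
                                      1e-5, 1e-5, w$config$rint, 1e-6)
  pr <- probability_report(w)
  expect_equal(max(pr$max_p), p_expect, tolerance = 1e-12)
})

test_that("free diffusion follows the 3D MSD law through the engine", {
  w <- open_world(n = 1000, D = 1e-6, seed = 5)
  x0 <- cbind(w$vol$x, w$vol$y, w$vol$z)  # empty until first release
  run_iterations(w, 1L)                    # release happens here
  start <- cbind(w$vol$x, w$vol$y, w$vol$z)[order(w$vol$id), ]
  run_iterations(w, 100L)
  end <- cbind(w$vol$x, w$vol$y, w$vol$z)[order(w$vol$id), ]
  expect_equal(nrow(end), 1000L)
  msd <- rowSums((end - start)^2)
  expected <- 6 * 1e-6 * 1e8 * 100 * 1e-6
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - expected), 3 * se)
})

test_that("surface diffusion follows the 2D MSD law on a flat face", {
  # wide flat box; molecules on the z- face, reflective cap edges
  # the tile step must be well below the diffusion step so that the
  # tile-center quantization of surface positions does not bias the walk
  txt <- c("begin parameters", "MCELL_DIFFUSION_CONSTANT_2D_s 1e-5",
           "end parameters",
           "begin molecule types", "s()", "end molecule types",
           "begin observables", "Molecules s s()", "end observables")
  mesh <- make_box(c(0, 0, 0.25), c(20, 20, 0.5))
  go <- geometry_object(mesh, "plate", regions = list(cap = c(1L, 2L)),
                        region_edges_reflective = "cap")
  b <- model_bundle(parse_bngl(txt), geometry = list(go),
                    releases = list(release_site(
                      "s()", shape = "surface", count = 400L,
                      object = "plate", region = "cap")),
                    config = simulation_config(seed = 8, count_stride = 500L))
  w <- build_world(b)
  run_iterations(w, 1L)
  tab0 <- molecule_table(w)
  run_iterations(w, 200L)
  tab1 <- molecule_table(w)
  m0 <- as.matrix(tab0[order(tab0$id), c("x", "y", "z")])
  m1 <- as.matrix(tab1[order(tab1$id), c("x", "y", "z")])
  msd <- rowSums((m1 - m0)^2)
  expected <- 4 * 1e-5 * 1e8 * 200 * 1e-6
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - expected), 4 * se)
})

test_that("a reflective box never leaks molecules", {
  w <- box_world(side = 0.5, n = 1000, D = 1e-5, seed = 3)
  run_iterations(w, 1000L)  # 1e6 molecule-steps
  expect_length(w$vol$id, 1000L)
  expect_true(all(abs(w$vol$x) <= 0.25 + 1e-9))
  expect_true(all(abs(w$vol$y) <= 0.25 + 1e-9))
  expect_true(all(abs(w$vol$z) <= 0.25 + 1e-9))
})

test_that("a constructed near-contact pair reacts at the collision point", {
  # huge rate constant -> p >> 1; the pair sits well inside r_int
  txt <- c("begin model", "begin parameters",
           "MCELL_DIFFUSION_CONSTANT_3D_A 1e-8",
           "MCELL_DIFFUSION_CONSTANT_3D_B 0",
           "MCELL_DIFFUSION_CONSTANT_3D_C 0",
           "kbig 1e12", "end parameters",
           "begin molecule types", "A()", "B()", "C()",
           "end molecule types",
           "begin observables", "Molecules C C()", "end observables",
           "begin reaction rules", "hit: A() + B() -> C() kbig",
           "end reaction rules", "end model")
  b <- model_bundle(parse_bngl(txt),
                    releases = list(
                      release_site("A()", shape = "points",
                                   points = matrix(c(0, 0, 0), 1)),
                      release_site("B()", shape = "points",
                                   points = matrix(c(2e-4, 0, 0), 1))),
                    config = simulation_config(seed = 4, count_stride = 1L))
  w <- build_world(b)
  run_iterations(w, 50L)
  expect_equal(tail(w$counts[, "C"], 1), 1)
  expect_length(w$vol$id, 1L)
  # the immobile product sits at the collision site, near the pair
  expect_lt(sqrt(w$vol$x^2 + w$vol$y^2 + w$vol$z^2), 0.01)
  # p > 1 is reported with the offending rule
  pr <- probability_report(w)
  expect_gt(pr$max_p[pr$rule == "hit"], 1)
})

test_that("events run in release -> diffuse -> count order", {
  # the t = 0 row precedes the first release; the released molecules are
  # visible in the t = dt row (counts are sampled after DiffuseReact)
  w <- open_world(n = 5, D = 1e-6, seed = 2, stride = 1L)
  run_iterations(w, 2L)
  expect_equal(w$counts[, "a"], c(0, 5, 5))
  expect_equal(w$counts[, "time"], c(0, 1e-6, 2e-6))
  expect_equal(w$time, 2e-6)
})

test_that("n = 0 iterations leaves the world untouched", {
  w <- open_world(n = 5, seed = 2)
  before <- list(w$time, w$iter, length(w$vol$id))
  run_iterations(w, 0L)
  expect_identical(list(w$time, w$iter, length(w$vol$id)), before)
})

test_that("unimolecular decay is exponential with the right rate", {
  w <- box_world(side = 1, n = 2000, D = 1e-6, seed = 6,
                 rules = "dec: a() -> 0 2000")
  run_iterations(w, 500L)  # t = 0.5 ms, expect N0 e^-1
  n <- length(w$vol$id)
  p <- exp(-2000 * 5e-4)
  se <- sqrt(2000 * p * (1 - p))
  expect_lt(abs(n - 2000 * p), 4 * se)
})

test_that("competing unimolecular pathways fire in proportion to rate", {
  w <- box_world(side = 1, n = 3000, D = 1e-6, seed = 7,
                 extra_types = c("x()", "y()"),
                 extra_params = c("MCELL_DIFFUSION_CONSTANT_3D_x 1e-6",
                                  "MCELL_DIFFUSION_CONSTANT_3D_y 1e-6"),
                 rules = c("px: a() -> x() 3000", "py: a() -> y() 1000"),
                 obs = c("Molecules x x()", "Molecules y y()"))
  run_iterations(w, 2000L)
  nx <- tail(w$counts[, "x"], 1); ny <- tail(w$counts[, "y"], 1)
  expect_gt(nx + ny, 2500)  # nearly all decayed
  phat <- nx / (nx + ny)
  se <- sqrt(0.75 * 0.25 / (nx + ny))
  expect_lt(abs(phat - 0.75), 4 * se)
})

test_that("surface releases by density and exclusion behave as specified", {
  b <- fixture_model("membrane_localization", seed = 1)  # full-size paper box
  w <- build_world(b)
  run_iterations(w, 1L)
  expect_length(w$surf$id, 3755L)
  # at most one molecule per tile
  occ <- w$geom$occup[w$geom$occup > 0]
  expect_equal(length(occ), length(unique(occ)))
  # zero-count release is a no-op
  w2 <- open_world(n = 0, seed = 1)
  run_iterations(w2, 1L)
  expect_length(w2$vol$id, 0L)
  # over-capacity surface release errors, naming the region
  b3 <- fixture_model("membrane_localization", seed = 1, face = 0.2,
                      length = 1, density_M = 80000)
  expect_error(run_iterations(build_world(b3), 1L), "vacant tiles")
})

test_that("identical seeds give identical trajectories (and cleanup too)", {
  mk <- function(seed, cleanup) {
    b <- fixture_model("autophosphorylation", seed = seed,
                       count_stride = 200L)
    b$config$cleanup_interval <- cleanup
    w <- build_world(b)
    run_iterations(w, 3000L)
    w
  }
  w1 <- mk(12, 10000L)
  w2 <- mk(12, 10000L)
  expect_identical(w1$counts, w2$counts)
  expect_identical(w1$vol, w2$vol)
  # aggressive cache cleanup must not change a single byte of the output
  w3 <- mk(12, 10L)
  expect_identical(w1$counts, w3$counts)
  f1 <- tempfile(); f3 <- tempfile()
  write_gdat(w1$counts, f1); write_gdat(w3$counts, f3)
  expect_identical(readLines(f1), readLines(f3))
  # different seed, different trajectory (positions certainly differ)
  w4 <- mk(13, 10000L)
  expect_false(identical(w1$vol, w4$vol))
})

test_that("reaction callbacks fire synchronously and can create molecules", {
  env <- new.env(); env$calls <- 0L
  w <- box_world(side = 1, n = 200, D = 1e-6, seed = 9,
                 extra_types = c("x()", "nt()"),
                 extra_params = c("MCELL_DIFFUSION_CONSTANT_3D_x 1e-6",
                                  "MCELL_DIFFUSION_CONSTANT_3D_nt 1e-6"),
                 rules = "fuse: a() -> x() 500",
                 obs = c("Molecules x x()", "Molecules nt nt()"))
  nt_id <- register_species(w$cache, parse_complex("nt()"), w$types)
  register_callback(w, "reaction", trigger = "fuse",
                    fn = function(time, rule, pos, ctx) {
                      env$calls <- env$calls + 1L
                      list(create = list(sp = rep(ctx$sp, 2L),
                                         x = rep(pos[1], 2),
                                         y = rep(pos[2], 2),
                                         z = rep(pos[3], 2)))
                    },
                    context = list(sp = nt_id))
  run_iterations(w, 1000L)
  fired <- w$fired[match("fuse", w$rule_names)]
  expect_gt(fired, 0)
  # invocation count equals the reaction-occurrence count, and each call
  # released two molecules at the triggering position
  expect_equal(env$calls, fired)
  expect_equal(tail(w$counts[, "nt"], 1), 2 * fired)
  expect_error(register_callback(w, "reaction", trigger = "nope",
                                 fn = identity), "unknown rule")
})

test_that("transparent and absorptive surface classes act per species", {
  # inner box transparent to a, absorptive to b
  txt <- c("begin parameters", "MCELL_DIFFUSION_CONSTANT_3D_a 1e-5",
           "MCELL_DIFFUSION_CONSTANT_3D_b 1e-5", "end parameters",
           "begin molecule types", "a()", "b()", "end molecule types",
           "begin observables", "Molecules a a()", "Molecules b b()",
           "end observables")
  outer <- geometry_object(make_box(c(0, 0, 0), c(1, 1, 1)), "outer")
  inner <- geometry_object(make_box(c(0, 0, 0), c(0.4, 0.4, 0.4)), "inner")
  b <- model_bundle(parse_bngl(txt), geometry = list(outer, inner),
                    releases = list(
                      release_site("a()", shape = "points",
                                   points = matrix(0, 50, 3)),
                      release_site("b()", shape = "points",
                                   points = matrix(0, 50, 3))),
                    surface_classes = list(
                      list(species = "a", object = "inner",
                           behavior = "transparent"),
                      list(species = "b", object = "inner",
                           behavior = "absorptive")),
                    config = simulation_config(seed = 10, count_stride = 50L))
  w <- build_world(b)
  run_iterations(w, 400L)
  tab <- molecule_table(w)
  a_pos <- tab[tab$species == "a()", c("x", "y", "z")]
  # some a escaped the inner box through its transparent wall
  expect_true(any(apply(abs(a_pos), 1, max) > 0.21))
  # every b was absorbed on its first wall contact
  expect_equal(tail(w$counts[, "b"], 1), 0)
  expect_equal(tail(w$counts[, "a"], 1), 50)
})

test_that("wall-hit callbacks observe collisions", {
  env <- new.env(); env$hits <- 0L
  w <- box_world(side = 0.2, n = 50, D = 1e-5, seed = 11)
  register_callback(w, "wall_hit", fn = function(time, sp, tri, pt, ctx) {
    env$hits <- env$hits + 1L
    NULL
  }, object = "CP")
  run_iterations(w, 50L)
  expect_gt(env$hits, 0L)
})
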