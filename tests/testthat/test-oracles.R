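# ODE and SSA oracles, low-pass peak detection, ensembles.

test_that("the ODE oracle matches the closed form for A+B->C", {
  m <- parse_bngl(system.file("extdata", "abc.bngl", package = "mcreact"))
  net <- expand_network(m)
  times <- seq(0, 6e-3, 2e-4)
  o <- ode_oracle(net, c("A()@CP" = 100, "B()@CP" = 100), times, volume = 1)
  cc <- 1e9 * 1e15 / 6.02214076e23   # per-pair rate in the 1 um^3 box
  closed <- 100 / (1 + cc * 100 * times)
  expect_equal(unname(o[, "A()@CP"]), closed, tolerance = 1e-6)
  # conservation: A + C constant
  expect_equal(unname(o[, "A()@CP"] + o[, "C()@CP"]), rep(100, length(times)),
               tolerance = 1e-8)
  # zero rates freeze the state
  net0 <- net; net0$reactions$rate <- 0
  o0 <- ode_oracle(net0, c("A()@CP" = 100, "B()@CP" = 100), times, volume = 1)
  expect_true(all(o0[, "A()@CP"] == 100))
})

test_that("the SNARE network conserves total snare count in the ODE", {
  m <- parse_bngl(system.file("extdata", "snare.bngl", package = "mcreact"))
  net <- expand_network(m)
  y0 <- stats::setNames(c(70, 5000),
                        c("snare(a~0,dv~1,s~0)@PM", "Ca()@CP"))
  y0 <- y0[names(y0) %in% net$species$label]
  expect_length(y0, 2L)
  times <- seq(0, 5e-3, 5e-4)
  o <- ode_oracle(net, y0, times, volume = 0.25)
  snare_cols <- grep("^snare", colnames(o))
  expect_equal(unname(rowSums(o[, snare_cols])), rep(70, length(times)),
               tolerance = 1e-7)
})

test_that("SSA means converge to the analytic decay and the ODE", {
  m <- parse_bngl(c("begin molecule types", "X()", "end molecule types",
                    "begin seed species", "X() 200", "end seed species",
                    "begin reaction rules", "d: X() -> 0 1000",
                    "end reaction rules"))
  net <- expand_network(m)
  times <- seq(0, 2e-3, 1e-4)
  tr <- sapply(1:256, function(s)
    ssa_oracle(net, c("X()" = 200), s, times, volume = 1)[, "X()"])
  mu <- rowMeans(tr)
  sem <- apply(tr, 1, stats::sd) / sqrt(ncol(tr))
  expect_true(all(abs(mu - 200 * exp(-1000 * times)) <= 3 * sem + 1e-9))
  # an empty network keeps counts constant
  m2 <- parse_bngl(c("begin molecule types", "X()", "end molecule types",
                     "begin seed species", "X() 7", "end seed species"))
  net2 <- expand_network(m2)
  s2 <- ssa_oracle(net2, c("X()" = 7), 1, times, volume = 1)
  expect_true(all(s2[, "X()"] == 7))
})

test_that("SSA ensemble mean tracks the ODE within 3 SEM for A+B->C", {
  m <- parse_bngl(system.file("extdata", "abc.bngl", package = "mcreact"))
  net <- expand_network(m)
  times <- seq(0, 4e-3, 4e-4)
  o <- ode_oracle(net, c("A()@CP" = 100, "B()@CP" = 100), times, volume = 1)
  tr <- sapply(1:512, function(s)
    ssa_oracle(net, c("A()@CP" = 100, "B()@CP" = 100), s, times,
               volume = 1)[, "C()@CP"])
  mu <- rowMeans(tr)
  sem <- apply(tr, 1, stats::sd) / sqrt(ncol(tr))
  # skip t=0 where both are exactly zero
  ix <- -1L
  expect_true(all(abs(mu[ix] - o[ix, "C()@CP"]) <= 3 * sem[ix] + 0.5))
})

test_that("low-pass peak detection recovers sinusoid periods", {
  t <- seq(0, 10, 0.01)
  expect_length(lowpass_peak_times(rep(3, length(t)), t, window = 21), 0L)
  clean <- sin(2 * pi * t / 2.5)
  pk <- lowpass_peak_times(clean, t, window = 21, min_prominence = 0.2)
  expect_true(all(abs(diff(pk) - 2.5) <= 0.011))
  set.seed(2)
  noisy <- clean + stats::rnorm(length(t), 0, sd = stats::sd(clean) / 5)
  pk2 <- lowpass_peak_times(noisy, t, window = 51, min_prominence = 0.2)
  expect_length(pk2, length(pk))
  expect_error(lowpass_peak_times(1:5, seq_len(5), window = 21),
               "shorter than filter width")
})

test_that("ensembles summarize per-seed runs and persist gdat files", {
  # deterministic fixture (no reactions): zero SD across seeds
  mkfix <- function(s) {
    txt <- c("begin parameters", "MCELL_DIFFUSION_CONSTANT_3D_a 0",
             "end parameters", "begin molecule types", "a()",
             "end molecule types", "begin observables", "Molecules a a()",
             "end observables")
    model_bundle(parse_bngl(txt),
                 releases = list(release_site("a()", shape = "points",
                                              points = matrix(0, 4, 3))),
                 config = simulation_config(seed = s, count_stride = 2L))
  }
  dir <- tempfile()
  es <- run_ensemble(mkfix, seeds = c(2, 9), iterations = 6L, out_dir = dir)
  expect_equal(unname(es$sd[, "a"]), rep(0, length(es$time)))
  expect_equal(unname(es$mean[nrow(es$mean), "a"]), 4)
  expect_length(list.files(dir, pattern = "gdat$"), 2L)
  back <- read_gdat(file.path(dir, "seed_00002.gdat"))
  expect_equal(unname(back[, "a"]), unname(es$trajectories[[1]][, "a"]))
})

test_that("one hybrid step applies the documented coupling cycle", {
  b <- fixture_model("clock_hybrid", seed = 3, volume_scale = 128)
  w <- build_world(b)
  # all counts zero at the start: R stays at zero through one step
  st <- clock_hybrid_step(w)
  expect_equal(st$value, 0)
  run_iterations(w, 40000L)
  r_now <- w$hybrid$value
  expect_true(is.finite(r_now) && r_now >= 0)
  # the continuous value is reported as a count column
  expect_true("R_free" %in% colnames(w$counts))
})
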