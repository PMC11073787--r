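# Model assembly from BNGL, observables, gdat/viz output, CLI.

abc_path <- system.file("extdata", "abc.bngl", package = "mcreact")

test_that("a BNGL file loads into a runnable spatial model", {
  b <- load_bngl_into_model(abc_path,
                            config = simulation_config(seed = 1,
                                                       count_stride = 10L))
  expect_s3_class(b, "mc_model_bundle")
  expect_length(b$geometry, 1L)
  # auto-generated box matches the declared compartment volume
  expect_equal(mesh_measures(b$geometry[[1]]$mesh)$volume, 1,
               tolerance = 1e-9)
  w <- build_world(b)
  run_iterations(w, 10L)
  expect_equal(unname(w$counts[2, c("A", "B")]), c(100, 100))
})

test_that("section-selective import leaves other parts untouched", {
  base <- load_bngl_into_model(abc_path)
  n_seeds <- length(base$bngl$seed_species)
  other <- c("begin parameters", "k2 7", "end parameters",
             "begin molecule types", "A()", "B()", "C()",
             "end molecule types",
             "begin seed species", "A() 1", "end seed species",
             "begin reaction rules", "r2: C() -> 0 k2",
             "end reaction rules")
  merged <- load_bngl_into_model(other, sections = "reaction rules",
                                 into = base)
  expect_length(merged$bngl$seed_species, n_seeds)  # seeds unchanged
  expect_equal(names(merged$bngl$reaction_rules), "r2")
  expect_error(load_bngl_into_model(abc_path, sections = "bogus"),
               "unknown section")
})

test_that("a mapped mesh with the wrong volume is rejected at 1%", {
  good <- make_box(c(0, 0, 0), c(1, 1, 1.005))     # 0.5% off: accepted
  b <- load_bngl_into_model(abc_path, compartment_map = list(CP = good))
  expect_s3_class(b, "mc_model_bundle")
  bad <- make_box(c(0, 0, 0), c(1, 1, 1.2))
  expect_error(load_bngl_into_model(abc_path,
                                    compartment_map = list(CP = bad)),
               "within 1%")
})

test_that("observable kinds count embeddings vs matching instances", {
  txt <- c("begin model", "begin parameters",
           "MCELL_DIFFUSION_CONSTANT_3D_A 1e-6", "end parameters",
           "begin molecule types", "A(c0~R~S,c0~R~S)", "end molecule types",
           "begin compartments", "CP 3 1", "end compartments",
           "begin seed species", "@CP:A(c0~R,c0~R) 1", "end seed species",
           "begin observables", "end observables",
           "begin reaction rules", "end reaction rules", "end model")
  b <- load_bngl_into_model(txt)
  w <- build_world(b)
  run_iterations(w, 1L)
  mol_obs <- list(kind = "Molecules", name = "m",
                  patterns = list("A(c0~R)"), scope = NA, count_rule = NA)
  sp_obs <- list(kind = "Species", name = "s",
                 patterns = list("A(c0~R)"), scope = NA, count_rule = NA)
  expect_equal(count_observable(w, mol_obs), 2)  # two embeddings
  expect_equal(count_observable(w, sp_obs), 1)   # one matching instance
  # empty world
  w0 <- open_world(0)
  expect_equal(count_observable(w0, list(kind = "Molecules", name = "m",
                                         patterns = list("a()"),
                                         scope = NA, count_rule = NA)), 0)
})

test_that("reaction-count observables accumulate firings", {
  w <- box_world(side = 1, n = 500, D = 1e-6, seed = 3,
                 rules = "dec: a() -> 0 1000")
  run_iterations(w, 500L)
  obs <- list(kind = "Molecules", name = "n_dec", patterns = list(),
              scope = NA, count_rule = "dec")
  expect_equal(count_observable(w, obs), 500 - length(w$vol$id))
})

test_that("gdat files round-trip bit-for-bit at formatted precision", {
  w <- box_world(side = 1, n = 50, D = 1e-6, seed = 4, stride = 5L)
  run_iterations(w, 20L)
  f <- tempfile(fileext = ".gdat")
  write_gdat(w$counts, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#\\s+time\\s+a")
  back <- read_gdat(f)
  expect_equal(colnames(back), colnames(w$counts))
  expect_equal(back, w$counts, ignore_attr = TRUE, tolerance = 1e-14)
  # column order matches declaration order
  b <- fixture_model("snare", seed = 1)
  ws <- build_world(b)
  run_iterations(ws, 1L)
  expect_equal(colnames(ws$counts),
               c("time", "Ca_free", "docked", "s5", "released"))
  # header-only file for empty series
  f2 <- tempfile()
  write_gdat(w$counts[0, , drop = FALSE], f2)
  expect_length(readLines(f2), 1L)
  expect_equal(nrow(read_gdat(f2)), 0L)
})

test_that("viz frames list every molecule with its position", {
  w <- open_world(n = 10, D = 1e-6, seed = 5)
  f <- tempfile(fileext = ".dat")
  write_viz_frame(w, 0L, f)
  expect_length(readLines(f), 1L)  # header only, empty world
  run_iterations(w, 3L)
  write_viz_frame(w, 3L, f)
  lines <- readLines(f)[-1]
  expect_length(lines, 10L)
  xyz <- do.call(rbind, lapply(strsplit(lines, " "), function(x)
    as.numeric(x[3:5])))
  tab <- molecule_table(w)
  expect_equal(xyz[order(as.integer(sapply(strsplit(lines, " "), `[`, 2))), ],
               as.matrix(tab[order(tab$id), c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-8)
  # surface molecules carry a normal vector
  bs <- fixture_model("membrane_localization", seed = 1, face = 0.2,
                      length = 1, n_A = 5, n_B = 5, density_M = 500)
  wsf <- build_world(bs)
  run_iterations(wsf, 1L)
  write_viz_frame(wsf, 1L, f)
  surf_lines <- grep("^M", readLines(f), value = TRUE)
  expect_true(all(lengths(strsplit(surf_lines, " ")) == 8L))
})

test_that("the CLI runs a config end to end", {
  dir <- tempfile(); dir.create(dir)
  file.copy(abc_path, file.path(dir, "abc.bngl"))
  cfg <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(model = "abc.bngl", iterations = 50L, dt = 1e-6,
                        seed = 3, count_stride = 10L,
                        output = "counts.gdat"), cfg)
  code <- cli_run(c("run", cfg, "--out", file.path(dir, "out")))
  expect_equal(code, 0L)
  got <- read_gdat(file.path(dir, "out", "counts.gdat"))
  expect_equal(nrow(got), 6L)  # t=0 plus one row per 10 iterations
  # BNGL export of a pure-BNGL model reproduces the chemistry
  exp_path <- file.path(dir, "exported.bngl")
  code2 <- cli_run(c("run", cfg, "--export-bngl", exp_path,
                     "--expand-network", "--out", file.path(dir, "out2")))
  expect_equal(code2, 0L)
  m2 <- parse_bngl(exp_path)
  expect_length(m2$reaction_rules, 1L)
  expect_true(file.exists(file.path(dir, "out2", "network.net")))
  # usage errors exit nonzero
  expect_equal(suppressMessages(cli_run(c("run", cfg, "--bogus"))), 1L)
  expect_equal(suppressMessages(cli_run(character())), 1L)
})
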