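# BNGL parsing, expression evaluation, and round-trip writing.

abc_path <- system.file("extdata", "abc.bngl", package = "mcreact")
snare_path <- system.file("extdata", "snare.bngl", package = "mcreact")

test_that("the minimal compartmental file parses to the expected model", {
  m <- parse_bngl(abc_path)
  expect_length(m$compartments, 1L)
  expect_equal(m$compartments$CP$dim, 3L)
  expect_equal(m$compartments$CP$size, 1)
  expect_length(m$seed_species, 2L)
  expect_equal(vapply(m$seed_species, `[[`, 0L, "count"), c(100L, 100L))
  expect_length(m$reaction_rules, 1L)
  r <- m$reaction_rules[[1]]
  expect_length(r$reactants, 2L)
  expect_length(r$products, 1L)
  expect_equal(r$rate, 1e9)
  # diffusion constants picked up from the magic parameters
  expect_equal(m$molecule_types$A$D, 1e-5)
  expect_equal(m$molecule_types$A$dim, 3L)
})

test_that("empty sections give empty collections, not errors", {
  m <- parse_bngl(c("begin parameters", "end parameters",
                    "begin molecule types", "end molecule types",
                    "begin seed species", "end seed species"))
  expect_length(m$molecule_types, 0L)
  expect_length(m$seed_species, 0L)
  expect_length(m$reaction_rules, 0L)
})

test_that("duplicate-component molecule types parse with shared state sets", {
  m <- parse_bngl(c("begin molecule types", "A(c0~R~S,c0~R~S)",
                    "end molecule types"))
  ty <- m$molecule_types$A
  expect_equal(ty$comp_names, c("c0", "c0"))
  expect_equal(ty$comp_states, list(c("R", "S"), c("R", "S")))
  expect_error(parse_bngl(c("begin molecule types", "A(c0~R~S,c0~R)",
                            "end molecule types")),
               "identical allowed states")
})

test_that("parameter arithmetic supports + - * / ^ with precedence", {
  m <- parse_bngl(c("begin parameters", "a 2", "b a^3 + 1",
                    "c (b - 3) * a / 4", "d -a + 2^2^2", "end parameters"))
  expect_equal(unname(m$parameters["b"]), 9)
  expect_equal(unname(m$parameters["c"]), 3)
  expect_equal(unname(m$parameters["d"]), 14)  # right-associative power
})

test_that("both compartment dialects are accepted", {
  g1 <- parse_complex("@CP:A(x!1).B(y!1)")
  g2 <- parse_complex("A(x!1).B(y!1)@CP")
  expect_equal(canonical_form(g1), canonical_form(g2))
})

test_that("unsupported and malformed input raises informative errors", {
  expect_error(parse_bngl(c("begin functions", "f() = 1", "end functions")),
               "unsupported feature")
  expect_error(parse_bngl(c("begin parameters", "x foo(2)",
                            "end parameters")), "function")
  expect_error(parse_bngl(c("begin parameters", "x undeclared_name",
                            "end parameters")), "undeclared identifier")
  expect_error(parse_bngl(c("begin molecule types", "A()",
                            "end molecule types",
                            "begin compartments", "CP 3 1",
                            "end compartments",
                            "begin seed species", "@NOPE:A() 5",
                            "end seed species")), "undeclared compartment")
  expect_error(parse_bngl("A() 5"), "outside any section")
  # line/column context present in the message
  err <- tryCatch(parse_bngl(c("begin parameters", "x 1 +", "end parameters")),
                  error = conditionMessage)
  expect_match(err, "line 2")
})

test_that("comments and line continuations are handled", {
  m <- parse_bngl(c("begin parameters  # trailing comment",
                    "k 1 + \\", "    2", "end parameters"))
  expect_equal(unname(m$parameters["k"]), 3)
})

test_that("write/parse round-trips preserve canonical model content", {
  for (path in c(abc_path, snare_path)) {
    m1 <- parse_bngl(path)
    m2 <- parse_bngl(strsplit(as.character(write_bngl(m1)), "\n")[[1]])
    expect_equal(m1$parameters, m2$parameters)
    expect_equal(names(m1$molecule_types), names(m2$molecule_types))
    expect_equal(names(m1$compartments), names(m2$compartments))
    expect_equal(
      vapply(m1$seed_species, function(s) canonical_form(s$graph), ""),
      vapply(m2$seed_species, function(s) canonical_form(s$graph), ""))
    expect_equal(vapply(m1$seed_species, `[[`, 0L, "count"),
                 vapply(m2$seed_species, `[[`, 0L, "count"))
    expect_equal(length(m1$reaction_rules), length(m2$reaction_rules))
    expect_equal(vapply(m1$reaction_rules, `[[`, 0, "rate"),
                 vapply(m2$reaction_rules, `[[`, 0, "rate"))
  }
})

test_that("the SNARE model has three molecule types and ten written rules", {
  m <- parse_bngl(snare_path)
  expect_length(m$molecule_types, 3L)
  # 7 reversible rules split at parse + 3 irreversible = 17 unidirectional
  expect_length(m$reaction_rules, 17L)
  base <- unique(sub("_rev$", "", names(m$reaction_rules)))
  expect_length(base, 10L)
})

test_that("spatial-only features are reported on BNGL export, not dropped", {
  b <- fixture_model("membrane_localization", seed = 1, face = 0.2,
                     length = 1, n_A = 10, n_B = 10)
  txt <- write_bngl(b)
  w <- attr(txt, "warnings")
  expect_true(length(w) > 0)
  expect_true(any(grepl("spatial location|geometry", w)))
  # the chemistry itself still round-trips
  m2 <- parse_bngl(strsplit(as.character(txt), "\n")[[1]])
  expect_length(m2$reaction_rules, length(b$bngl$reaction_rules))
})
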