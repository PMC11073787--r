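# Compartment-class resolution, derived diffusion constants, rate units.

types_vt <- list(
  A = list(name = "A", comp_names = character(), comp_states = list(),
           D = 1e-6, dim = 3L),
  T = list(name = "T", comp_names = character(), comp_states = list(),
           D = 1e-8, dim = 2L))
comps_epc <- list(
  EC = list(name = "EC", dim = 3L, size = 10, parent = NA_character_),
  PM = list(name = "PM", dim = 2L, size = 1, parent = "EC"),
  CP = list(name = "CP", dim = 3L, size = 1, parent = "PM"))

test_that("@OUT/@IN resolve to the outer and inner compartments", {
  r <- mc_rule("transport",
               list(parse_complex("A@OUT"), parse_complex("T")),
               list(parse_complex("A@IN"), parse_complex("T")), 1)
  rr <- resolve_compartment_classes(r, "PM", comps_epc, types_vt)
  expect_equal(rr$reactants[[1]]$compartment, "EC")
  expect_equal(rr$products[[1]]$compartment, "CP")
  expect_equal(rr$reactants[[2]]$compartment, "PM")
  expect_equal(rr$products[[2]]$compartment, "PM")
})

test_that("rules without classes pass through unchanged", {
  r <- mc_rule("plain", list(parse_complex("A"), parse_complex("T")),
               list(parse_complex("A")), 2)
  expect_identical(resolve_compartment_classes(r, "PM", comps_epc, types_vt),
                   r)
})

test_that("classes on non volume+surface rules are rejected", {
  r2 <- mc_rule("bad", list(parse_complex("A@IN"), parse_complex("A@OUT")),
                list(parse_complex("A@IN"), parse_complex("A@OUT")), 1)
  expect_error(resolve_compartment_classes(r2, "PM", comps_epc, types_vt),
               "volume and one surface")
  r3 <- mc_rule("uni", list(parse_complex("A@IN")),
                list(parse_complex("A@OUT")), 1)
  expect_error(resolve_compartment_classes(r3, "PM", comps_epc, types_vt),
               "bimolecular")
  # membrane without an inner compartment
  comps2 <- comps_epc[c("EC", "PM")]
  r <- mc_rule("t", list(parse_complex("A@OUT"), parse_complex("T")),
               list(parse_complex("A@IN"), parse_complex("T")), 1)
  expect_error(resolve_compartment_classes(r, "PM", comps2, types_vt),
               "no inner compartment")
})

test_that("complex diffusion constants follow the combining rules", {
  tys <- list(
    X = list(name = "X", comp_names = "b", comp_states = list(character()),
             D = 1e-6, dim = 3L),
    Z = list(name = "Z", comp_names = "b", comp_states = list(character()),
             D = 0, dim = 3L),
    S = list(name = "S", comp_names = "b", comp_states = list(character()),
             D = 1e-8, dim = 2L))
  # monomer keeps its own D
  expect_equal(derive_diffusion_constant(parse_complex("X(b)"), tys)$D, 1e-6)
  # any zero-D subunit freezes the whole complex
  dd <- derive_diffusion_constant(parse_complex("X(b!1).Z(b!1)"), tys)
  expect_equal(dd$D, 0)
  # volume homodimer: D0 * 2^(-1/3)
  dd2 <- derive_diffusion_constant(parse_complex("X(b!1).X(b!1)"), tys)
  expect_equal(dd2$D, 1e-6 * 2^(-1 / 3))
  expect_equal(dd2$dim, 3L)
  # any surface subunit makes a surface complex; only surface subunits enter
  dd3 <- derive_diffusion_constant(parse_complex("X(b!1).S(b!1)"), tys)
  expect_equal(dd3$dim, 2L)
  expect_equal(dd3$D, 1e-8)
  dd4 <- derive_diffusion_constant(parse_complex("S(b!1).S(b!1)"), tys)
  expect_equal(dd4$D, 1e-8 * 2^(-1 / 2))
})

test_that("rate-unit conversions match dimensional analysis and invert", {
  # 10^9 M^-1 s^-1 -> ~1.6605 um^3 N^-1 s^-1 (factor 1e15 / Avogadro)
  k <- convert_rate_units(1e9, "vol_bimol", "mcell", "bng")
  expect_equal(k, 1e9 * 1e15 / 6.02214076e23)
  expect_equal(k, 1.66054, tolerance = 1e-4)
  # surface-surface: x membrane thickness 0.01 um
  expect_equal(convert_rate_units(1, "surf_bimol", "mcell", "bng"), 0.01)
  # unimolecular rates are untouched
  expect_equal(convert_rate_units(5, "unimol", "mcell", "bng"), 5)
  # mutually inverse
  for (ctx in c("vol_bimol", "surf_bimol", "unimol")) {
    k0 <- 3.7
    expect_equal(convert_rate_units(
      convert_rate_units(k0, ctx, "mcell", "bng"), ctx, "bng", "mcell"), k0)
  }
  expect_error(convert_rate_units(1, "nope", "mcell", "bng"),
               "unknown reaction context")
})
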