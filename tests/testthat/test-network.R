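# Species/reaction caches and bounded network expansion.

simple_types <- function() {
  parse_bngl(c("begin parameters",
               "MCELL_DIFFUSION_CONSTANT_3D_A 1e-6",
               "MCELL_DIFFUSION_CONSTANT_3D_B 1e-6",
               "MCELL_DIFFUSION_CONSTANT_3D_C 1e-6",
               "end parameters",
               "begin molecule types", "A()", "B()", "C()",
               "end molecule types"))$molecule_types
}

test_that("lookup_or_expand computes pathways once and caches the object", {
  tys <- simple_types()
  rules <- list(mc_rule("mk", list(parse_complex("A"), parse_complex("B")),
                        list(parse_complex("C")), 2))
  cache <- species_cache()
  a <- register_species(cache, parse_complex("A()"), tys)
  b <- register_species(cache, parse_complex("B()"), tys)
  cls1 <- lookup_or_expand(cache, c(a, b), rules, tys)
  expect_length(cls1$pathways, 1L)
  expect_equal(cls1$pathways[[1]]$rule, "mk")
  prod <- cls1$pathways[[1]]$products
  expect_equal(species_label(cache, prod), "C()")
  # (B, A) gives the same class object; repeated calls hit the cache
  cls2 <- lookup_or_expand(cache, c(b, a), rules, tys)
  expect_identical(cls1, cls2)
  # pair with no applicable rule: empty class, still cached
  cls3 <- lookup_or_expand(cache, c(a, a), rules, tys)
  expect_length(cls3$pathways, 0L)
  expect_identical(lookup_or_expand(cache, c(a, a), rules, tys), cls3)
})

test_that("cache cleanup evicts only zero-instance species", {
  tys <- simple_types()
  rules <- list(mc_rule("mk", list(parse_complex("A"), parse_complex("B")),
                        list(parse_complex("C")), 2))
  cache <- species_cache()
  a <- register_species(cache, parse_complex("A()"), tys)
  b <- register_species(cache, parse_complex("B()"), tys)
  invisible(lookup_or_expand(cache, c(a, b), rules, tys))
  cid <- cache$by_label[["C()"]]
  cache$info[[a]]$count <- 5L
  cache$info[[b]]$count <- 2L
  cache$info[[cid]]$count <- 0L
  n <- cleanup_caches(cache)
  expect_gte(n, 1L)
  expect_null(cache$info[[cid]]$graph)       # evicted
  expect_false(is.null(cache$info[[a]]$graph))
  # the id survives eviction: re-registration gets the old id back
  expect_identical(register_species(cache, parse_complex("C()"), tys), cid)
  # nothing to evict when everything is alive
  cache$info[[cid]]$count <- 1L
  expect_equal(cleanup_caches(cache), 0L)
})

test_that("tiny networks expand to the hand-enumerated fixed point", {
  m <- parse_bngl(system.file("extdata", "abc.bngl", package = "mcreact"))
  net <- expand_network(m)
  expect_equal(nrow(net$species), 3L)
  expect_equal(nrow(net$reactions), 1L)
  # 2-site independent phosphorylation, forward only: 4 species, 4 reactions
  m2 <- parse_bngl(c(
    "begin molecule types", "K(a~0~1,b~0~1)", "end molecule types",
    "begin seed species", "K(a~0,b~0) 10", "end seed species",
    "begin reaction rules",
    "pa: K(a~0) -> K(a~1) 1",
    "pb: K(b~0) -> K(b~1) 1",
    "end reaction rules"))
  net2 <- expand_network(m2)
  expect_equal(nrow(net2$species), 4L)
  expect_equal(nrow(net2$reactions), 4L)
})

test_that("expansion is independent of seed ordering and respects limits", {
  path <- system.file("extdata", "snare.bngl", package = "mcreact")
  m <- parse_bngl(path)
  net1 <- expand_network(m)
  net2 <- expand_network(m, seeds = c("Ca()@CP", "@PM:snare(s~0,a~0,dv~1)"))
  key <- function(net) sort(paste(net$reactions$rule, net$reactions$r1,
                                  net$reactions$r2, net$reactions$products))
  expect_setequal(net1$species$label, net2$species$label)
  expect_equal(nrow(net1$reactions), nrow(net2$reactions))
  expect_error(expand_network(m, max_species = 10L), "bounded expansion")
})

test_that("net-style export lists every species and reaction", {
  m <- parse_bngl(system.file("extdata", "abc.bngl", package = "mcreact"))
  net <- expand_network(m)
  f <- tempfile(fileext = ".net")
  write_net(net, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^  \\d+ ", lines)), nrow(net$species))
  expect_true(any(grepl("->", lines)))
})

test_that("symmetric rules do not double-count the identical-pair ordering", {
  tys <- list(A = list(name = "A", comp_names = character(),
                       comp_states = list(), D = 1e-6, dim = 3L),
              AA = list(name = "AA", comp_names = character(),
                        comp_states = list(), D = 1e-6, dim = 3L))
  rules <- list(mc_rule("dim", list(parse_complex("A"), parse_complex("A")),
                        list(parse_complex("AA")), 1))
  cache <- species_cache()
  a <- register_species(cache, parse_complex("A()"), tys)
  cls <- lookup_or_expand(cache, c(a, a), rules, tys)
  expect_length(cls$pathways, 1L)
})
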