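# Pattern embedding enumeration and rule application by graph rewriting.

test_that("embeddings respect states, bonds and the unbound convention", {
  s <- parse_complex("A(c0~R,c0~S)")
  expect_length(match_pattern(parse_complex("A(c0~R)"), s), 1L)
  expect_length(match_pattern(parse_complex("A"), s), 1L)
  # a listed component without bond syntax means unbound
  s2 <- parse_complex("A(c0~R!1,c0~S).B(c1!1)")
  expect_length(match_pattern(parse_complex("A(c0)"), s2), 1L)
  e <- match_pattern(parse_complex("A(c0)"), s2)[[1]]
  expect_equal(s2$comp_state[e$comp], "S")
  # wildcards: !+ requires a bond, !? matches either
  expect_length(match_pattern(parse_complex("A(c0!+)"), s2), 1L)
  expect_length(match_pattern(parse_complex("A(c0!?)"), s2), 2L)
  expect_length(match_pattern(parse_complex("A(c0~S!+)"), s2), 0L)
})

test_that("pattern automorphisms collapse equivalent embeddings", {
  # symmetric two-site pattern on a symmetric species: one distinct embedding
  p <- parse_complex("A(c0~R,c0~R)")
  s <- parse_complex("A(c0~R,c0~R)")
  expect_length(match_pattern(p, s), 1L)
  # but two embeddings when the pattern picks one site of a mixed species
  expect_length(match_pattern(parse_complex("A(c0~R)"),
                              parse_complex("A(c0~R,c0~R)")), 2L)
})

test_that("compartment-tagged patterns match only that compartment", {
  s <- parse_complex("A(x)@CP")
  expect_length(match_pattern(parse_complex("A(x)@CP"), s), 1L)
  expect_length(match_pattern(parse_complex("A(x)@EC"), s), 0L)
  expect_length(match_pattern(parse_complex("A(x)"), s), 1L)
})

test_that("a bond-and-state rewrite produces one connected product", {
  # two-site A binds B through its R-state site, which switches to S
  r <- mc_rule("bind",
               list(parse_complex("A(c0~R)"), parse_complex("B(c1)")),
               list(parse_complex("A(c0~S!1).B(c1!1)")), 1)
  prods <- apply_rule(r, list(parse_complex("A(c0~R,c0~S)"),
                              parse_complex("B(c1,c2~X)")))
  expect_length(prods, 1L)
  expect_equal(canonical_form(prods[[1]]),
               canonical_form(parse_complex("A(c0~S,c0~S!1).B(c1!1,c2~X)")))
})

test_that("molecule replacement and unbinding work", {
  r1 <- mc_rule("mk", list(parse_complex("A"), parse_complex("B")),
                list(parse_complex("C")), 1)
  prods <- apply_rule(r1, list(parse_complex("A"), parse_complex("B")))
  expect_length(prods, 1L)
  expect_equal(canonical_form(prods[[1]]), "C()")

  r2 <- mc_rule("unbind", list(parse_complex("A(c0!1).B(c1!1)")),
                list(parse_complex("A(c0)"), parse_complex("B(c1)")), 1)
  dimer <- parse_complex("A(c0~R!1).B(c1!1,c2~X)")
  prods2 <- apply_rule(r2, list(dimer))
  expect_length(prods2, 2L)
  # jointly isomorphic to the monomers with the bond removed
  labs <- sort(vapply(prods2, canonical_form, ""))
  expect_equal(labs, sort(c(canonical_form(parse_complex("A(c0~R)")),
                            canonical_form(parse_complex("B(c1,c2~X)")))))
})

test_that("degradation rules delete molecules together with their bonds", {
  r <- mc_rule("deg", list(parse_complex("B")), list(), 1)
  prods <- apply_rule(r, list(parse_complex("A(c0~R!1).B(c1!1)")))
  expect_length(prods, 1L)
  expect_equal(canonical_form(prods[[1]]), "A(c0~R)")
})

test_that("rewrites conserve elementary molecules except where rules say", {
  set.seed(7)
  bind <- mc_rule("b", list(parse_complex("A(x~u)"), parse_complex("B(s)")),
                  list(parse_complex("A(x~u!1).B(s!1)")), 1)
  checked <- 0L
  for (i in 1:16) {
    ga <- random_species_graph(sample(1:3, 1))
    gb <- random_species_graph(sample(1:3, 1))
    embs <- rule_embeddings(bind, list(ga, gb))
    for (e in embs) {
      prods <- apply_rule(bind, list(ga, gb), e)
      before <- sort(c(ga$mol_type, gb$mol_type))
      after <- sort(unlist(lapply(prods, `[[`, "mol_type")))
      expect_equal(after, before)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})
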