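# Multiplier expansion, macrocycle/chain repeat-unit expansion, annotation
# stripping, and molecular-formula derivation.

test_that("multiplier expansion yields the exhaustive notation", {
  out <- csm_serialize(csm_expand_multipliers("[Co+2].[O-]N(=O)=O{2}.O{6}"))
  expect_identical(out, "[Co+2].[O-]N(=O)=O.[O-]N(=O)=O.O.O.O.O.O.O")

  # identity on multiplier-free notations
  x <- csm_parse("C.O")
  expect_identical(csm_serialize(csm_expand_multipliers(x)), "C.O")

  # conservation of total multiplicity over generated notations
  for (seed in 1:25) {
    gen <- csm_generate(seed, "mixed")
    expanded <- csm_expand_multipliers(gen$notation)
    expect_equal(length(expanded$components), gen$truth$total_multiplicity)
    expect_true(all(vapply(expanded$components, `[[`, 1L, "multiplier") == 1L))
  }
})

test_that("macrocycle expansion joins k units head-to-tail into one ring", {
  unit <- csm_parse_smiles("CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}")
  ring <- csm_expand_ring(unit)
  expect_equal(length(ring$atoms), 4L * length(unit$atoms))
  joins <- Filter(function(b) isTRUE(b$join), ring$bonds)
  expect_equal(length(joins), 4L)
  expect_equal(length(ring$bonds), 4L * length(unit$bonds) + 4L)
  # boundary markers are consumed; per-unit substituent markers are copied
  markers <- unlist(lapply(ring$atoms, function(a)
    vapply(a$annotations, `[[`, "", "marker")))
  expect_equal(sum(markers == "-R"), 4L)
  expect_false(any(markers %in% c("-", "+r")))
  # the expanded graph serialises and re-parses
  g2 <- csm_parse_smiles(csm_serialize_graph(ring))
  expect_equal(length(g2$atoms), length(ring$atoms))

  # smallest macrocycle: a two-atom unit with n=2 gives a 4-ring
  small <- csm_expand_ring("C{-}C{+rn=2}")
  expect_equal(length(small$atoms), 4L)
  expect_equal(length(small$bonds), 4L)

  expect_error(csm_expand_ring("C{-}C{+r}"), class = "csm_error_bad_repeat_unit")
  expect_error(csm_expand_ring("CC{+rn=4}"), class = "csm_error_bad_repeat_unit")
  expect_error(csm_expand_ring("C{-}C{+rn=1}"), class = "csm_error_bad_repeat_unit")
})

test_that("removing join bonds from an expanded ring leaves k unit copies", {
  for (k in 2:6) {
    unit_s <- sprintf("CC(C)OC{-}CC{+rn=%d}", k)
    unit <- csm_parse_smiles(unit_s)
    ring <- csm_expand_ring(unit)
    expect_equal(length(ring$atoms), k * length(unit$atoms))
    kept <- Filter(function(b) !isTRUE(b$join), ring$bonds)
    ig <- igraph::make_empty_graph(length(ring$atoms), directed = FALSE)
    ig <- igraph::add_edges(ig, unlist(lapply(kept, function(b) c(b$a, b$b))))
    comps <- igraph::components(ig)
    expect_equal(comps$no, k)
    unit_plain <- graph_as_igraph(unit)
    for (cid in seq_len(comps$no)) {
      sub <- igraph::induced_subgraph(ig, which(comps$membership == cid))
      expect_equal(igraph::vcount(sub), length(unit$atoms))
      expect_equal(igraph::ecount(sub), length(unit$bonds))
    }
  }
})

test_that("chain expansion concatenates units and leaves dangling bonds", {
  unit <- csm_parse_smiles("N{-}=P{+n}(OCCOCCOC)(OCCOCCOC)")
  chain <- csm_expand_chain(unit, k = 3)
  expect_equal(length(chain$atoms), 3L * length(unit$atoms))
  expect_equal(length(chain$bonds), 3L * length(unit$bonds) + 2L)
  # terminal open bonds are marked as structural-unit boundaries
  unit_markers <- which(vapply(chain$atoms, function(a)
    any(vapply(a$annotations, function(x) x$marker_class == "unit", TRUE)), TRUE))
  expect_equal(length(unit_markers), 2L)

  one <- csm_expand_chain("N{-}=P{+n}(OCCOCCOC)(OCCOCCOC)", k = 1)
  expect_equal(length(one$atoms), length(unit$atoms))

  # an open-ended unit needs an explicit count
  expect_error(csm_expand_chain("N{-}=P{+n}(OC)(OC)"), class = "csm_error_need_count")
  expect_error(csm_expand_chain("NP(OC)(OC)", k = 2), class = "csm_error_bad_repeat_unit")

  for (k in c(2L, 5L)) {
    g <- csm_expand_chain("C{-}O[SiH2]{+n}", k = k)
    expect_equal(length(g$atoms), 3L * k)
  }
})

test_that("annotation stripping distinguishes drop from strict policy", {
  fig <- "O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}"
  plain <- csm_strip_annotations(fig, policy = "drop")
  expect_identical(plain, "O[Si](O)(O)CCCn1ccnc1")
  reparsed <- csm_parse_smiles(plain)
  expect_equal(sum(vapply(reparsed$atoms, function(a) length(a$annotations), 0L)), 0L)

  # a plain notation passes through unchanged
  expect_identical(csm_strip_annotations("CCO"), "CCO")

  # a group must not silently become a radical
  expect_error(csm_strip_annotations("C{-}", policy = "strict"),
               class = "csm_error_strict_annotations")
  # pure stereodescriptors do not change identity
  expect_identical(csm_strip_annotations("C{R}(N)CC", policy = "strict"), "C(N)CC")
  expect_error(csm_strip_annotations("{*SiO2}", policy = "drop"),
               class = "csm_error_not_molecular")

  # dropped output always re-parses with zero annotations
  for (seed in 1:20) {
    gen <- csm_generate(seed, "annotated")
    out <- csm_strip_annotations(gen$notation, policy = "drop")
    g <- csm_parse_smiles(out)
    expect_equal(sum(vapply(g$atoms, function(a) length(a$annotations), 0L)) +
                   length(g$caa), 0L)
    expect_equal(length(g$atoms), gen$truth$atoms)
  }
})

test_that("molecular formulas include implicit hydrogens and charge", {
  f <- csm_formula("[O-]N(=O)=O")
  expect_equal(as.list(f$flattened[c("N", "O")]), list(N = 1L, O = 3L))
  expect_equal(f$charge, -1L)
  expect_false("H" %in% names(f$flattened))

  f <- csm_formula("O")
  expect_equal(as.list(f$flattened[c("H", "O")]), list(H = 2L, O = 1L))
  expect_equal(f$charge, 0L)

  f <- csm_formula("[CH3]")
  expect_equal(as.list(f$flattened[c("C", "H")]), list(C = 1L, H = 3L))

  f <- csm_formula("c1ccccc1")
  expect_equal(as.list(f$flattened[c("C", "H")]), list(C = 6L, H = 6L))

  # graph formula matches an independently written composition
  expect_true(csm_compare_sfn(csm_formula("[O-]N(=O)=O"),
                              csm_parse_sfn("NO3(1-)")))
  expect_true(csm_compare_sfn(csm_formula("CCO"), csm_parse_sfn("C2H6O")))

  expect_error(csm_formula("[*H2]=[*]"), class = "csm_error_wildcard_formula")
})
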