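# Square-bracket atomic codes, graph construction, serialisation and the
# dialect's bond/wildcard/stereo rules.

test_that("square-bracket atomic codes parse their fields", {
  a <- csm_parse_sqc("Co+2")
  expect_equal(a$symbol, "Co")
  expect_equal(a$charge, 2L)
  expect_equal(a$hcount, 0L)

  a <- csm_parse_sqc("*H2")
  expect_true(a$wildcard)
  expect_equal(a$hcount, 2L)

  a <- csm_parse_sqc("CH4")
  expect_equal(a$symbol, "C")
  expect_equal(a$hcount, 4L)
  expect_equal(a$charge, 0L)

  a <- csm_parse_sqc("13CH3")
  expect_equal(a$isotope, 13L)
  expect_equal(a$hcount, 3L)

  expect_equal(csm_parse_sqc("O-")$charge, -1L)
  expect_equal(csm_parse_sqc("N++")$charge, 2L)
  expect_equal(csm_parse_sqc("Fe-3")$charge, -3L)
  expect_equal(csm_parse_sqc("H")$symbol, "H")
  expect_true(csm_parse_sqc("se")$aromatic)

  expect_error(csm_parse_sqc("Xx"), class = "csm_error_unknown_element")
  expect_error(csm_parse_sqc("C+2-"), class = "csm_error_bad_sqc")
  expect_error(csm_parse_sqc(""), class = "csm_error_bad_sqc")
})

test_that("graphs are built with branches, rings and default bonds", {
  g <- csm_parse_smiles("[O-]N(=O)=O")
  expect_equal(length(g$atoms), 4L)
  expect_equal(length(g$bonds), 3L)
  expect_equal(sort(vapply(g$bonds, `[[`, "", "order")), c("-", "=", "="))
  expect_equal(g$atoms[[1]]$charge, -1L)
  expect_equal(g$atoms[[2]]$charge, 0L)

  g <- csm_parse_smiles("[*H2]=[*]")
  expect_equal(length(g$atoms), 2L)
  expect_true(all(vapply(g$atoms, `[[`, TRUE, "wildcard")))
  expect_equal(g$bonds[[1]]$order, "=")

  g <- csm_parse_smiles("C1CC1")
  expect_equal(length(g$atoms), 3L)
  expect_equal(length(g$bonds), 3L)
  expect_true(any(vapply(g$bonds, function(b) b$ring, TRUE)))

  # benzene against a hand-built adjacency oracle
  g <- csm_parse_smiles("c1ccccc1")
  expect_equal(length(g$atoms), 6L)
  expect_equal(length(g$bonds), 6L)
  expect_true(all(vapply(g$atoms, `[[`, TRUE, "aromatic")))
  expect_true(all(vapply(g$bonds, `[[`, "", "order") == ":"))
  got <- sort(vapply(g$bonds, function(b) paste(sort(c(b$a, b$b)), collapse = "-"), ""))
  oracle <- sort(c("1-2", "2-3", "3-4", "4-5", "5-6", "1-6"))
  expect_equal(got, oracle)

  # two-digit ring labels
  g <- csm_parse_smiles("C%10CCC%10")
  expect_equal(length(g$bonds), 4L)
})

test_that("stereo glyphs, bare wildcards and bond-context rules are enforced", {
  expect_error(csm_parse_smiles("C@C"), class = "csm_error_stereo_glyph")
  expect_error(csm_parse_smiles("C/C=C"), class = "csm_error_stereo_glyph")
  expect_error(csm_parse_smiles("C\\C"), class = "csm_error_stereo_glyph")
  expect_error(csm_parse_smiles("*C"), class = "csm_error_bare_wildcard")
  # ~ and $ bonds require square-bracket encoding on both endpoints
  expect_error(csm_parse_smiles("C~C"), class = "csm_error_bond_context")
  expect_error(csm_parse_smiles("[C]$C"), class = "csm_error_bond_context")
  expect_silent(csm_parse_smiles("[C]~[C]"))
  expect_silent(csm_parse_smiles("[Re]$[Re]"))
  expect_error(csm_parse_smiles("C1CC"), class = "csm_error_unclosed_ring")
  expect_error(csm_parse_smiles("C(C"), class = "csm_error_unclosed_branch")
  expect_error(csm_parse_smiles("C)C"), class = "csm_error_unclosed_branch")
  expect_error(csm_parse_smiles("C=1CC-1"), class = "csm_error_ring_bond_conflict")
  expect_silent(csm_parse_smiles("C=1CC=1"))
  expect_error(csm_parse_smiles("C=#C"), class = "csm_error_dangling_bond")
  expect_error(csm_parse_smiles("C="), class = "csm_error_dangling_bond")
  expect_warning(csm_parse_smiles("[C]&[C]"), class = "csm_warning_ambig_bond")
})

test_that("atom and bond counts are conserved by branches and ring closures", {
  # same heavy-atom multiset written linear, branched, and with a ring label
  linear <- csm_parse_smiles("CCCC")
  branched <- csm_parse_smiles("CC(C)C")
  expect_equal(length(linear$atoms), length(branched$atoms))
  expect_equal(length(linear$bonds), length(branched$bonds))
  ringy <- csm_parse_smiles("C1CCC1")
  expect_equal(length(ringy$atoms), 4L)
  expect_equal(length(ringy$bonds), 5L - 1L)
})

test_that("serialisation is a parse fixed point, with and without source text", {
  for (s in c("[O-]N(=O)=O", "c1ccccc1", "O{-|i=-2}", "C1CC1",
              "CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}")) {
    g <- csm_parse_smiles(s)
    expect_identical(csm_serialize_graph(g), s)
    # force the writer path and check structural equality via isomorphism
    g2 <- g
    g2$src <- NULL
    rewritten <- csm_serialize_graph(g2)
    g3 <- csm_parse_smiles(rewritten)
    expect_equal(length(g3$atoms), length(g$atoms))
    expect_equal(length(g3$bonds), length(g$bonds))
    expect_true(graphs_isomorphic(g, g3))
  }
})

test_that("generated components parse to the generator's recorded counts", {
  for (seed in 1:30) {
    gen <- csm_generate(seed, "plain")
    g <- csm_parse_smiles(gen$notation)
    expect_equal(length(g$atoms), gen$truth$atoms)
    expect_equal(length(g$bonds), gen$truth$bonds)
  }
})
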