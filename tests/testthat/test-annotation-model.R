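# Marker classification, dictionary parsing with recursive values, anchoring
# and relative pointers.

test_that("marker classification partitions the annotation space", {
  cases <- list(
    list("R", "stereo", "R"),
    list("Z", "stereo", "Z"),
    list("-", "unit", "-"),
    list("~", "unit", "~"),
    list("-|sfn=SiO2", "geam", "-|"),
    list("-R", "geam", "-R"),
    list("-X", "geam", "-X"),
    list("=Y", "geam", "=Y"),
    list("~|", "geam", "~|"),
    list(".|", "geam", ".|"),
    list("!re=+", "mdam", "!r"),
    list("!H", "mdam", "!H"),
    list("+rn=4", "opam", "+r"),
    list("+Rn=4-16", "opam", "+R"),
    list("+n", "opam", "+n"),
    list("+Lc=C", "opam", "+L"),
    list("aq", "ssam", "aq"),
    list("Dp", "miam", "Dp")
  )
  for (cs in cases) {
    ann <- csm_parse_annotation(cs[[1]])
    expect_equal(ann$marker_class, cs[[2]], label = cs[[1]])
    expect_equal(ann$marker, cs[[3]], label = cs[[1]])
    # classification is stable under re-serialisation
    again <- csm_parse_annotation(csm_serialize_annotation(ann))
    expect_equal(again$marker_class, ann$marker_class)
  }
  # atom-anchored vs component-anchored
  expect_equal(csm_parse_annotation("R")$anchor_kind, "atom")
  expect_equal(csm_parse_annotation("+rn=4")$anchor_kind, "atom")
  expect_equal(csm_parse_annotation("aq")$anchor_kind, "component")
  # the typeset ". |" marker normalises to ".|"
  expect_equal(csm_parse_annotation(". |")$marker, ".|")
})

test_that("invalid markers and unknown registry entries are handled", {
  expect_error(csm_parse_annotation("Q"), class = "csm_error_bad_marker")
  expect_error(csm_parse_annotation("-Z"), class = "csm_error_bad_marker")
  expect_error(csm_parse_annotation("=R"), class = "csm_error_bad_marker")
  expect_error(csm_parse_annotation("!x"), class = "csm_error_bad_marker")
  expect_error(csm_parse_annotation("+q"), class = "csm_error_bad_marker")
  expect_error(csm_parse_annotation(""), class = "csm_error_bad_annotation")
  expect_warning(csm_parse_annotation("zz"), class = "csm_warning_unknown_ssam")
  expect_warning(csm_parse_annotation("Qx"), class = "csm_warning_unknown_miam")
  expect_warning(csm_parse_dictionary("foo=1"), class = "csm_warning_unknown_key")
  # $-prefixed keys are customer-defined and bypass the registry
  expect_silent(e <- csm_parse_dictionary("$mykey=1"))
  expect_true(e[[1]]$customer)
})

test_that("dictionaries split at depth zero, type values, and round-trip", {
  entries <- csm_parse_dictionary("sfn=SiO2;i=-2")
  expect_equal(vapply(entries, `[[`, "", "key"), c("sfn", "i"))
  expect_equal(entries[[2]]$parsed$value, -2L)
  expect_identical(csm_serialize_dictionary(entries), "sfn=SiO2;i=-2")

  # a value holding a full recursive notation stays one entry
  val <- "CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}"
  entries <- csm_parse_dictionary(paste0("c=", val))
  expect_equal(length(entries), 1L)
  expect_identical(entries[[1]]$raw, val)
  expect_equal(entries[[1]]$parsed$type, "notation")
  inner <- entries[[1]]$parsed$value
  expect_s3_class(inner, "csm_notation")
  expect_equal(length(inner$components[[1]]$content$atoms), 12L)
  expect_identical(csm_serialize_dictionary(entries), paste0("c=", val))

  entries <- csm_parse_dictionary("n=4-16")
  expect_equal(entries[[1]]$parsed$type, "range")
  expect_equal(entries[[1]]$parsed$lo, 4L)
  expect_equal(entries[[1]]$parsed$hi, 16L)

  entries <- csm_parse_dictionary("e=+")
  expect_equal(entries[[1]]$parsed$type, "charge")
  expect_equal(entries[[1]]$parsed$value, 1L)

  expect_equal(csm_parse_dictionary(""), list())
  expect_error(csm_parse_dictionary("novalue"), class = "csm_error_bad_dictionary")
  expect_error(csm_parse_dictionary("n=1;n=2"), class = "csm_error_bad_dictionary")
  expect_error(csm_parse_dictionary("1bad=x"), class = "csm_error_bad_dictionary")
})

test_that("annotations anchor to the nearest preceding atomic node", {
  g <- csm_parse_smiles("O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}")
  markers <- lapply(g$atoms, function(a) vapply(a$annotations, `[[`, "", "marker"))
  expect_equal(markers[[1]], "-|")
  expect_equal(markers[[3]], "-|")
  expect_equal(markers[[11]], "-R")   # imidazolium N bearing the alkyl mark
  expect_equal(markers[[12]], "!r")   # the ring-closing aromatic carbon
  expect_equal(length(unlist(markers)), 4L)

  # a component-anchored class may not be followed by more atoms
  expect_error(csm_parse_smiles("C{aq}C"), class = "csm_error_bad_annotation_position")
  # an atom-anchored class needs an atomic node code directly before it
  expect_error(csm_parse_smiles("CC(C){R}"),
               class = "csm_error_bad_annotation_position")
  expect_error(csm_parse_smiles("{R}C"),
               class = "csm_error_bad_annotation_position")
  # boundary descriptors ':' '&' '~' require square-bracket anchors
  expect_error(csm_parse_smiles("C{~}"), class = "csm_error_unit_anchor")
  expect_silent(csm_parse_smiles("[C]{~}"))
})

test_that("relative pointers resolve along atom appearance order", {
  g <- csm_parse_smiles("O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}")
  ann <- g$atoms[[3]]$annotations[[1]]
  target <- csm_resolve_pointer(ann, g, 3L)
  expect_equal(target, 1L)
  sfn_entry <- Filter(function(e) e$key == "sfn",
                      g$atoms[[target]]$annotations[[1]]$entries)
  expect_equal(sfn_entry[[1]]$raw, "SiO2")

  # unit offset on a two-atom graph
  g2 <- csm_parse_smiles("[C]{-|sfn=MgO}[C]{-|i=-1}")
  expect_equal(csm_resolve_pointer(g2$atoms[[2]]$annotations[[1]], g2, 2L), 1L)

  # out-of-range and missing-target errors
  g3 <- csm_parse_smiles("[C]{-|i=-5}C")
  expect_error(csm_resolve_pointer(g3$atoms[[1]]$annotations[[1]], g3, 1L),
               class = "csm_error_bad_pointer")
  g4 <- csm_parse_smiles("CC[C]{-|i=-1}")
  expect_error(csm_resolve_pointer(g4$atoms[[3]]$annotations[[1]], g4, 3L),
               class = "csm_error_bad_pointer")
})

test_that("planted pointer pairs in generated fixtures are recovered", {
  found <- 0L
  for (seed in 1:30) {
    gen <- csm_generate(seed, "annotated")
    if (is.null(gen$truth$pointer)) next
    g <- csm_parse_smiles(gen$notation)
    anchor <- gen$truth$pointer$anchor
    anns <- g$atoms[[anchor]]$annotations
    ptr <- Filter(function(a) !is.null(entry_by_key(a, "i")), anns)
    expect_gte(length(ptr), 1L)
    expect_equal(csm_resolve_pointer(ptr[[1]], g, anchor), gen$truth$pointer$target)
    found <- found + 1L
  }
  expect_gte(found, 10L)
})
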