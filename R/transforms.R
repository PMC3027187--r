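# Structure-level rewrites: multiplier expansion to exhaustive form,
# repeat-unit expansion of macrocycles (+r) and linear chains (+n),
# annotation stripping, and molecular-formula derivation from a graph.

#' Expand multipliers to the exhaustive notation
#'
#' Replaces every component carrying a multiplier `m` with `m` consecutive
#' copies of the component (multiplier 1), so that serialisation yields the
#' exhaustive notation.
#'
#' @param x A `csm_notation` or a notation string.
#' @return A `csm_notation` with all multipliers expanded.
#' @examples
#' csm_serialize(csm_expand_multipliers("[Co+2].[O-]N(=O)=O{2}.O{6}"))
#' @export
csm_expand_multipliers <- function(x) {
  if (is.character(x)) x <- csm_parse(x)
  out <- list()
  for (comp in x$components) {
    m <- comp$multiplier
    comp$multiplier <- 1L
    out <- c(out, rep(list(comp), m))
  }
  x$components <- out
  x$src <- NULL
  x
}

csm_find_marked_atoms <- function(g, class, marker = NULL) {
  hits <- list()
  for (k in seq_along(g$atoms)) {
    for (ann in g$atoms[[k]]$annotations) {
      if (ann$marker_class == class &&
          (is.null(marker) || identical(ann$marker, marker))) {
        hits[[length(hits) + 1L]] <- list(atom = k, ann = ann)
      }
    }
  }
  hits
}

csm_drop_atom_annotation <- function(atom, marker_class, marker = NULL) {
  keep <- vapply(atom$annotations, function(a) {
    !(a$marker_class == marker_class && (is.null(marker) || identical(a$marker, marker)))
  }, TRUE)
  atom$annotations <- atom$annotations[keep]
  atom
}

# Copy the unit's atoms/bonds k times; per-unit annotations are retained on
# every copy except the boundary (+r/+n and unit) markers being resolved.
csm_replicate_unit <- function(g, k, drop_classes) {
  natoms <- length(g$atoms)
  atoms <- list()
  bonds <- list()
  for (j in seq_len(k)) {
    off <- (j - 1L) * natoms
    for (a in g$atoms) {
      for (cl in drop_classes) a <- csm_drop_atom_annotation(a, cl$class, cl$marker)
      atoms[[length(atoms) + 1L]] <- a
    }
    for (b in g$bonds) {
      b$a <- b$a + off
      b$b <- b$b + off
      bonds[[length(bonds) + 1L]] <- b
    }
  }
  list(atoms = atoms, bonds = bonds, natoms = natoms)
}

csm_boundary_order <- function(marker) {
  if (!marker %in% c("-", "=", "#", ":")) {
    csm_abort(sprintf("boundary descriptor '%s' cannot form an explicit join bond", marker),
              "incompatible_boundary")
  }
  marker
}

#' Expand a macrocyclic repeat unit
#'
#' A unit graph carrying exactly one structural-unit boundary annotation
#' (the open bond at the head atom) and one `+r` operational annotation with
#' an `n=k` entry (k >= 2) is rewritten as a macrocycle: k copies of the
#' unit joined head-to-tail, the `+r` atom of each copy bonded to the
#' boundary atom of the next, and the last copy closed back onto the first.
#' The join-bond order is taken from the boundary descriptor. All other
#' annotations are copied per unit; join bonds are flagged `join = TRUE`.
#'
#' @param g A `csm_graph` (or component string) encoding the repeat unit.
#' @return A `csm_graph` of the expanded macrocycle.
#' @examples
#' ring <- csm_expand_ring("CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}")
#' length(ring$atoms)
#' @export
csm_expand_ring <- function(g) {
  if (is.character(g)) g <- csm_parse_smiles(g)
  units <- csm_find_marked_atoms(g, "unit")
  reps <- csm_find_marked_atoms(g, "opam", "+r")
  if (length(units) != 1L || length(reps) != 1L) {
    csm_abort("ring expansion needs exactly one boundary annotation and one '+r' annotation",
              "bad_repeat_unit")
  }
  e <- csm_dict_entry(reps[[1]]$ann, "n")
  if (is.null(e) || is.null(e$parsed) || e$parsed$type != "int") {
    csm_abort("'+r' annotation must carry an integer 'n' entry", "bad_repeat_unit")
  }
  k <- e$parsed$value
  if (k < 2L) csm_abort("repeat count must be at least 2", "bad_repeat_unit")
  order <- csm_boundary_order(units[[1]]$ann$marker)

  rep_unit <- csm_replicate_unit(
    g, k,
    list(list(class = "unit", marker = NULL), list(class = "opam", marker = "+r"))
  )
  u <- units[[1]]$atom
  r <- reps[[1]]$atom
  for (j in seq_len(k)) {
    from <- (j - 1L) * rep_unit$natoms + r
    to <- (j %% k) * rep_unit$natoms + u
    rep_unit$bonds[[length(rep_unit$bonds) + 1L]] <-
      list(a = from, b = to, order = order, explicit = order != "-",
           ring = TRUE, join = TRUE)
  }
  structure(list(atoms = rep_unit$atoms, bonds = rep_unit$bonds, caa = list(),
                 src = NULL),
            class = "csm_graph")
}

#' Expand a linear-chain repeat unit
#'
#' A unit graph carrying one `+n` operational annotation (the open tail
#' bond) and one structural-unit boundary annotation (the open head bond) is
#' concatenated `k` times tail-to-head. The terminal open bonds stay
#' dangling: the first copy keeps its boundary annotation, and the last
#' copy's `+n` atom receives one with the same descriptor.
#'
#' @param g A `csm_graph` (or component string) with a `+n` annotation.
#' @param k Number of repeat units; defaults to the `n=` entry of the `+n`
#'   annotation when present (an open-ended macromolecule has none, and then
#'   `k` must be supplied).
#' @return A `csm_graph` of the expanded chain.
#' @examples
#' chain <- csm_expand_chain("N{-}=P{+n}(OCCOCCOC)(OCCOCCOC)", k = 3)
#' length(chain$atoms)
#' @export
csm_expand_chain <- function(g, k = NULL) {
  if (is.character(g)) g <- csm_parse_smiles(g)
  reps <- csm_find_marked_atoms(g, "opam", "+n")
  if (length(reps) != 1L) {
    csm_abort("chain expansion needs exactly one '+n' annotation", "bad_repeat_unit")
  }
  units <- csm_find_marked_atoms(g, "unit")
  if (length(units) != 1L) {
    csm_abort("chain expansion needs exactly one boundary annotation (the head)",
              "bad_repeat_unit")
  }
  if (is.null(k)) {
    e <- csm_dict_entry(reps[[1]]$ann, "n")
    if (!is.null(e) && !is.null(e$parsed) && e$parsed$type == "int") {
      k <- e$parsed$value
    } else {
      csm_abort("open-ended '+n' unit: an explicit repeat count k is required",
                "need_count")
    }
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) csm_abort("repeat count must be at least 1", "bad_repeat_unit")
  order <- csm_boundary_order(units[[1]]$ann$marker)
  boundary_ann <- units[[1]]$ann

  rep_unit <- csm_replicate_unit(
    g, k,
    list(list(class = "unit", marker = NULL), list(class = "opam", marker = "+n"))
  )
  u <- units[[1]]$atom
  r <- reps[[1]]$atom
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      from <- (j - 1L) * rep_unit$natoms + r
      to <- j * rep_unit$natoms + u
      rep_unit$bonds[[length(rep_unit$bonds) + 1L]] <-
        list(a = from, b = to, order = order, explicit = order != "-",
             ring = FALSE, join = TRUE)
    }
  }
  # dangling bonds: boundary annotation on the first head and the last tail
  head_ann <- boundary_ann
  head_ann$span <- NULL
  rep_unit$atoms[[u]]$annotations <-
    c(rep_unit$atoms[[u]]$annotations, list(head_ann))
  tail_idx <- (k - 1L) * rep_unit$natoms + r
  rep_unit$atoms[[tail_idx]]$annotations <-
    c(rep_unit$atoms[[tail_idx]]$annotations, list(head_ann))
  structure(list(atoms = rep_unit$atoms, bonds = rep_unit$bonds, caa = list(),
                 src = NULL),
            class = "csm_graph")
}

#' Strip annotations from a notation
#'
#' Removes curly-brace annotations from the SMILES-form components of a
#' notation, yielding plain SMILES. Under `policy = "strict"`, annotations
#' that change the chemical identity of the encoded species — structural
#' unit boundaries, group environments and operational annotations (e.g.
#' `C{-}`, a methyl group, which must not silently become the methyl radical
#' `[CH3]`) — make the call an error listing the offending markers.
#'
#' @param x A `csm_notation` or notation string. All components must be
#'   SMILES-form (a formula or alias component has no molecular part).
#' @param policy `"drop"` (delete all annotations) or `"strict"`.
#' @return A plain SMILES notation string (multipliers retained).
#' @examples
#' csm_strip_annotations("O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}")
#' @export
csm_strip_annotations <- function(x, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (is.character(x)) x <- csm_parse(x)
  parts <- vapply(x$components, function(comp) {
    if (comp$form != "smiles") {
      csm_abort(sprintf("component '%s' has no molecular part to strip", comp$text),
                "not_molecular")
    }
    g <- comp$content
    anns <- c(unlist(lapply(g$atoms, `[[`, "annotations"), recursive = FALSE),
              g$caa)
    if (policy == "strict") {
      bad <- vapply(anns, function(a) a$marker_class %in% c("unit", "geam", "opam"), TRUE)
      if (any(bad)) {
        csm_abort(sprintf("annotations alter the chemical identity and cannot be dropped: %s",
                          paste(unique(vapply(anns[bad], `[[`, "", "marker")),
                                collapse = ", ")),
                  "strict_annotations")
      }
    }
    text <- comp$text
    spans <- lapply(anns, `[[`, "span")
    spans <- spans[!vapply(spans, is.null, TRUE)]
    if (length(spans)) {
      ord <- order(vapply(spans, `[[`, 1L, 1L), decreasing = TRUE)
      for (sp in spans[ord]) {
        text <- paste0(substr(text, 1L, sp[[1]] - 1L),
                       substr(text, sp[[2]] + 1L, nchar(text)))
      }
    }
    if (comp$multiplier > 1L) paste0(text, "{", comp$multiplier, "}") else text
  }, "")
  paste(parts, collapse = ".")
}

#' Molecular formula of a graph
#'
#' Derives the elemental composition of a molecular graph, materialising
#' implicit hydrogens on bare organic-subset atoms from the standard valence
#' table (B 3; C 4; N 3,5; O 2; P 3,5; S 2,4,6; halogens 1; aromatic bonds
#' count 1.5) and counting explicit square-bracket hydrogen counts as
#' written. Isotope-labelled atoms are counted as separate species. Net
#' charge is the sum of atomic charges. The result is comparable with
#' [csm_compare_sfn()], cross-checking graph and formula encodings of the
#' same species.
#'
#' @param g A `csm_graph` or component string.
#' @return A `csm_sfn` composition.
#' @examples
#' csm_formula("[O-]N(=O)=O")
#' @export
csm_formula <- function(g) {
  if (is.character(g)) g <- csm_parse_smiles(g)
  counts <- integer(0)
  hydrogens <- 0L
  charge <- 0L
  deg <- numeric(length(g$atoms))
  for (b in g$bonds) {
    o <- csm_bond_order_num(b$order)
    deg[[b$a]] <- deg[[b$a]] + o
    deg[[b$b]] <- deg[[b$b]] + o
  }
  add <- function(key, n) {
    counts[key] <<- (if (key %in% names(counts)) counts[[key]] else 0L) + n
  }
  for (k in seq_along(g$atoms)) {
    at <- g$atoms[[k]]
    if (at$wildcard) {
      csm_abort("molecular formula is undefined for wildcard atoms", "wildcard_formula")
    }
    add(csm_species_key(at$symbol, at$isotope), 1L)
    charge <- charge + at$charge
    if (at$is_sqc) {
      hydrogens <- hydrogens + at$hcount
    } else {
      val <- CSM_VALENCES[[at$symbol]]
      used <- deg[[k]]
      v <- val[val >= used]
      h <- if (length(v)) as.integer(round(v[[1]] - used)) else 0L
      hydrogens <- hydrogens + max(h, 0L)
    }
  }
  if (hydrogens > 0L) add("H", hydrogens)
  counts <- counts[order(names(counts))]
  items <- lapply(names(counts), function(nm) {
    iso <- NA_integer_
    sym <- nm
    if (startsWith(nm, "^")) {
      iso <- as.integer(gsub("[^0-9]", "", nm))
      sym <- gsub("[\\^0-9]", "", nm)
    }
    list(kind = "element", symbol = sym, isotope = iso, count = counts[[nm]])
  })
  root <- list(kind = "group", items = items, count = 1L)
  structure(
    list(root = root, flattened = csm_flatten_sfn(root), charge = as.integer(charge),
         src = NULL),
    class = "csm_sfn"
  )
}
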