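# Molecular-graph parser for SMILES-form components of the annotated
# dialect. Differences from plain SMILES:
#   * curly-brace annotations may follow an atomic node code (after its
#     ring-closure digits) or sit at the end of the component;
#   * '~' (unspecified) and '$' (quadruple) are bond symbols, and both of
#     their endpoints must be square-bracket encoded;
#   * the atomic wildcard '*' must always be square-bracket encoded;
#   * the stereo glyphs '@', '/' and '\' are rejected outright — stereo is
#     expressed through annotations (D/E/L/R/S/Z).
# No aromaticity perception, kekulisation or valence checking is performed:
# aromatic flags and bond orders are purely syntactic.

csm_atom <- function(symbol, aromatic = FALSE, is_sqc = FALSE, wildcard = FALSE,
                     isotope = NA_integer_, hcount = NA_integer_, charge = 0L,
                     src = NULL) {
  list(symbol = symbol, aromatic = aromatic, is_sqc = is_sqc,
       wildcard = wildcard, isotope = isotope, hcount = hcount,
       charge = charge, annotations = list(), src = src)
}

#' Parse a square-bracket atomic code
#'
#' Parses the text between `[` and `]`: optional isotope digits, the element
#' symbol (or the `*` wildcard, which is only legal in bracket form),
#' optional attached-hydrogen count (`H`, `H2`, ...; zero when absent) and
#' optional charge (`+`, `-`, `+2`, `--`, ...).
#'
#' @param token Text between the brackets, e.g. `"Co+2"`.
#' @return An atom record (plain list) with fields `symbol`, `aromatic`,
#'   `is_sqc`, `wildcard`, `isotope`, `hcount`, `charge`.
#' @examples
#' csm_parse_sqc("Co+2")
#' csm_parse_sqc("*H2")
#' @export
csm_parse_sqc <- function(token) {
  if (!nzchar(token)) csm_abort("empty square-bracket atomic code", "bad_sqc")
  rest <- token
  isotope <- NA_integer_
  m <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(m)) {
    isotope <- as.integer(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  if (!nzchar(rest)) csm_abort(sprintf("no symbol in '[%s]'", token), "bad_sqc")

  aromatic <- FALSE
  wildcard <- FALSE
  if (startsWith(rest, "*")) {
    wildcard <- TRUE
    symbol <- "*"
    rest <- substr(rest, 2L, nchar(rest))
  } else {
    two <- substr(rest, 1L, 2L)
    one <- substr(rest, 1L, 1L)
    if (grepl("^[A-Z][a-z]$", two) && csm_is_element(two)) {
      symbol <- two
    } else if (grepl("^[A-Z]$", one) && csm_is_element(one)) {
      symbol <- one
    } else if (two %in% CSM_AROMATIC_SQC) {
      symbol <- two
      aromatic <- TRUE
    } else if (one %in% CSM_AROMATIC_SQC) {
      symbol <- one
      aromatic <- TRUE
    } else {
      csm_abort(sprintf("unknown element symbol in '[%s]'", token),
                "unknown_element")
    }
    rest <- substr(rest, nchar(symbol) + 1L, nchar(rest))
    if (aromatic) {
      symbol <- paste0(toupper(substr(symbol, 1L, 1L)),
                       substr(symbol, 2L, nchar(symbol)))
    }
  }

  hcount <- 0L
  if (startsWith(rest, "H") && symbol != "H") {
    rest <- substr(rest, 2L, nchar(rest))
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m)) {
      hcount <- as.integer(m)
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    } else {
      hcount <- 1L
    }
  }

  charge <- 0L
  if (nzchar(rest)) {
    if (grepl("^\\++$", rest)) charge <- nchar(rest)
    else if (grepl("^-+$", rest)) charge <- -nchar(rest)
    else if (grepl("^\\+[0-9]+$", rest)) charge <- as.integer(substr(rest, 2L, nchar(rest)))
    else if (grepl("^-[0-9]+$", rest)) charge <- -as.integer(substr(rest, 2L, nchar(rest)))
    else csm_abort(sprintf("malformed square-bracket atomic code '[%s]'", token),
                   "bad_sqc")
    charge <- as.integer(charge)
  }

  csm_atom(symbol, aromatic = aromatic, is_sqc = TRUE, wildcard = wildcard,
           isotope = isotope, hcount = hcount, charge = charge,
           src = paste0("[", token, "]"))
}

csm_find_matching <- function(chars, open, open_ch = "{", close_ch = "}") {
  depth <- 0L
  for (i in open:length(chars)) {
    if (chars[[i]] == open_ch) depth <- depth + 1L
    else if (chars[[i]] == close_ch) {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  csm_abort(sprintf("unclosed '%s'", open_ch), "unbalanced", offset = open - 1L)
}

#' Parse a SMILES-form component into a molecular graph
#'
#' Builds the molecular graph of one component: atoms in order of
#' appearance, branches via parentheses, ring bonds via digits and `%nn`
#' labels, default bond single (aromatic between two lower-case aromatic
#' atoms). Curly-brace annotations directly following an atomic node code
#' (only ring-closure digits may intervene) are anchored to that atom;
#' state-and-shape and miscellaneous annotations, and blocks after the last
#' atom, are anchored to the component.
#'
#' @param text A SMILES-form component notation (no top-level dots, no
#'   multiplier).
#' @return An object of class `csm_graph`: `atoms` (list of atom records,
#'   each carrying its `annotations`), `bonds` (list of edges with fields
#'   `a`, `b`, `order`, `ring`), `caa` (component-anchored annotations) and
#'   `src` (the source text, used for byte-identical round trips).
#' @examples
#' g <- csm_parse_smiles("[O-]N(=O)=O")
#' length(g$atoms)
#' @export
csm_parse_smiles <- function(text) {
  if (!nzchar(text)) csm_abort("empty component", "empty_component")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()
  bonds <- list()
  caa <- list()
  ann_spans <- list()      # character spans of annotation blocks, for stripping
  branch_stack <- integer(0)
  last_atom <- 0L
  pending <- NULL          # pending explicit bond symbol
  rings <- list()          # label -> list(atom, sym)
  can_aaa <- FALSE
  caa_seen <- FALSE
  i <- 1L

  fail <- function(msg, class) csm_abort(msg, class, offset = i - 1L)

  check_not_after_caa <- function() {
    if (caa_seen) {
      fail("component-anchored annotations must terminate the component",
           "bad_annotation_position")
    }
  }

  add_bond <- function(a, b, sym, explicit, ring = FALSE) {
    if (is.null(sym)) {
      sym <- if (atoms[[a]]$aromatic && atoms[[b]]$aromatic) ":" else "-"
      explicit <- FALSE
    }
    if (sym %in% c("~", "$") && (!atoms[[a]]$is_sqc || !atoms[[b]]$is_sqc)) {
      fail(sprintf("atoms joined by a '%s' bond must both be square-bracket encoded", sym),
           "bond_context")
    }
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, order = sym,
                                         explicit = explicit, ring = ring)
  }

  add_atom <- function(atom) {
    check_not_after_caa()
    atoms[[length(atoms) + 1L]] <<- atom
    idx <- length(atoms)
    if (last_atom > 0L) {
      add_bond(last_atom, idx, pending, explicit = !is.null(pending))
    } else if (!is.null(pending)) {
      fail("bond symbol with no preceding atom", "dangling_bond")
    }
    pending <<- NULL
    last_atom <<- idx
    can_aaa <<- TRUE
  }

  close_or_open_ring <- function(label) {
    check_not_after_caa()
    if (last_atom == 0L) fail("ring-closure digit with no preceding atom", "unclosed_ring")
    sym <- pending
    pending <<- NULL
    if (!is.null(rings[[label]])) {
      r <- rings[[label]]
      if (r$atom == last_atom) fail("ring bond to the same atom", "unclosed_ring")
      use <- NULL
      explicit <- FALSE
      if (!is.null(r$sym) && !is.null(sym)) {
        if (!identical(r$sym, sym)) {
          fail(sprintf("conflicting bond symbols '%s'/'%s' on ring label %s",
                       r$sym, sym, label), "ring_bond_conflict")
        }
        use <- sym; explicit <- TRUE
      } else if (!is.null(r$sym)) { use <- r$sym; explicit <- TRUE }
      else if (!is.null(sym)) { use <- sym; explicit <- TRUE }
      add_bond(r$atom, last_atom, use, explicit, ring = TRUE)
      rings[[label]] <<- NULL
    } else {
      rings[[label]] <<- list(atom = last_atom, sym = sym)
    }
    # ring digits may sit between an atomic node code and its annotations
  }

  while (i <= n) {
    ch <- chars[[i]]

    if (ch %in% c("@", "/", "\\")) {
      fail(sprintf("stereo glyph '%s' is not accepted; use a stereodescriptor annotation (D/E/L/R/S/Z)", ch),
           "stereo_glyph")
    }

    if (ch %in% CSM_BOND_SYMS) {
      check_not_after_caa()
      if (!is.null(pending)) fail("two consecutive bond symbols", "dangling_bond")
      if (ch == "&") {
        csm_warn("'&' used in bond position: stored as an ambiguous bond", "ambig_bond")
      }
      pending <- ch
      can_aaa <- FALSE
      i <- i + 1L
      next
    }

    if (ch == "(") {
      check_not_after_caa()
      if (last_atom == 0L) fail("branch with no preceding atom", "unclosed_branch")
      if (!is.null(pending)) fail("bond symbol before '('", "dangling_bond")
      branch_stack <- c(branch_stack, last_atom)
      can_aaa <- FALSE
      i <- i + 1L
      next
    }

    if (ch == ")") {
      check_not_after_caa()
      if (!length(branch_stack)) fail("unmatched ')'", "unclosed_branch")
      if (!is.null(pending)) fail("dangling bond symbol before ')'", "dangling_bond")
      last_atom <- branch_stack[[length(branch_stack)]]
      branch_stack <- branch_stack[-length(branch_stack)]
      can_aaa <- FALSE
      i <- i + 1L
      next
    }

    if (grepl("^[0-9]$", ch)) {
      close_or_open_ring(ch)
      i <- i + 1L
      next
    }

    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(text, i + 1L, i + 2L))) {
        fail("'%' ring label must be followed by two digits", "unclosed_ring")
      }
      close_or_open_ring(substr(text, i + 1L, i + 2L))
      i <- i + 3L
      next
    }

    if (ch == "[") {
      close <- csm_find_matching(chars, i, "[", "]")
      add_atom(csm_parse_sqc(substr(text, i + 1L, close - 1L)))
      i <- close + 1L
      next
    }

    if (ch == "{") {
      close <- csm_find_matching(chars, i, "{", "}")
      interior <- substr(text, i + 1L, close - 1L)
      ann <- csm_parse_annotation(interior)
      ann$span <- c(i, close)
      if (ann$anchor_kind == "component") {
        caa_seen <- TRUE
        caa[[length(caa) + 1L]] <- ann
      } else {
        check_not_after_caa()
        if (!can_aaa || last_atom == 0L) {
          fail(sprintf("atom-anchored annotation {%s} must directly follow an atomic node code",
                       interior), "bad_annotation_position")
        }
        atoms[[last_atom]]$annotations <-
          c(atoms[[last_atom]]$annotations, list(ann))
      }
      i <- close + 1L
      next
    }

    if (ch == "*") fail("the atomic wildcard must be square-bracket encoded ([*])",
                        "bare_wildcard")

    if (grepl("^[A-Z]$", ch)) {
      check_not_after_caa()
      two <- substr(text, i, i + 1L)
      if (two %in% CSM_ORGANIC_2) {
        add_atom(csm_atom(two, src = two))
        i <- i + 2L
        next
      }
      if (ch %in% CSM_ORGANIC_1) {
        add_atom(csm_atom(ch, src = ch))
        i <- i + 1L
        next
      }
      fail(sprintf("'%s' is not in the organic subset; use square-bracket encoding", ch),
           "unknown_element")
    }

    if (ch %in% CSM_AROMATIC_BARE) {
      check_not_after_caa()
      add_atom(csm_atom(toupper(ch), aromatic = TRUE, src = ch))
      i <- i + 1L
      next
    }

    if (ch == ".") fail("'.' inside a component", "empty_component")
    fail(sprintf("unexpected character '%s'", ch), "unexpected_char")
  }

  if (!is.null(pending)) csm_abort("dangling bond symbol at end of component", "dangling_bond")
  if (length(branch_stack)) csm_abort("unclosed branch '('", "unclosed_branch")
  open_rings <- names(rings)[!vapply(rings, is.null, TRUE)]
  if (length(open_rings)) {
    csm_abort(sprintf("unclosed ring label(s): %s", paste(open_rings, collapse = ", ")),
              "unclosed_ring")
  }
  if (!length(atoms)) csm_abort("component contains no atoms", "empty_component")

  g <- structure(
    list(atoms = atoms, bonds = bonds, caa = caa, src = text),
    class = "csm_graph"
  )
  csm_validate_anchors(g)
  g
}

# Structural-unit boundary descriptors ':', '&' and '~' require the anchor
# atom to be square-bracket encoded; '-', '=', '#' are fine on bare
# organic-subset atoms (which carry no isotope or charge by construction).
csm_validate_anchors <- function(g) {
  for (k in seq_along(g$atoms)) {
    at <- g$atoms[[k]]
    for (ann in at$annotations) {
      if (ann$marker_class == "unit" && ann$marker %in% c(":", "&", "~") &&
          !at$is_sqc) {
        csm_abort(sprintf("boundary descriptor '%s' requires a square-bracket encoded anchor atom",
                          ann$marker), "unit_anchor")
      }
    }
  }
  invisible(g)
}

# ---------------------------------------------------------------------------
# Serialisation

csm_default_bond <- function(g, a, b) {
  if (g$atoms[[a]]$aromatic && g$atoms[[b]]$aromatic) ":" else "-"
}

csm_format_anc <- function(atom) {
  if (!is.null(atom$src)) return(atom$src)
  if (!atom$is_sqc) {
    return(if (atom$aromatic) tolower(atom$symbol) else atom$symbol)
  }
  sym <- if (atom$wildcard) "*" else if (atom$aromatic) tolower(atom$symbol) else atom$symbol
  iso <- if (!is.na(atom$isotope)) as.character(atom$isotope) else ""
  h <- if (!is.na(atom$hcount) && atom$hcount > 0L) {
    if (atom$hcount == 1L) "H" else paste0("H", atom$hcount)
  } else ""
  chg <- if (atom$charge > 0L) {
    if (atom$charge == 1L) "+" else paste0("+", atom$charge)
  } else if (atom$charge < 0L) {
    if (atom$charge == -1L) "-" else paste0("-", abs(atom$charge))
  } else ""
  paste0("[", iso, sym, h, chg, "]")
}

#' Serialise a molecular graph to a component notation
#'
#' Graphs that still carry their source text round-trip byte-identically.
#' Graphs constructed programmatically (e.g. by repeat-unit expansion) are
#' written by a depth-first spanning-tree walk from the first atom, with
#' ring-closure labels for the remaining edges, so that
#' parse-serialise-parse is a fixed point.
#'
#' @param g A `csm_graph`.
#' @return A component notation string.
#' @export
csm_serialize_graph <- function(g) {
  if (!is.null(g$src)) return(g$src)
  natoms <- length(g$atoms)
  adj <- vector("list", natoms)
  for (e in seq_along(g$bonds)) {
    b <- g$bonds[[e]]
    adj[[b$a]] <- c(adj[[b$a]], list(list(to = b$b, edge = e)))
    adj[[b$b]] <- c(adj[[b$b]], list(list(to = b$a, edge = e)))
  }
  visited <- logical(natoms)
  edge_used <- logical(length(g$bonds))
  ring_at <- vector("list", natoms)   # atom -> list(list(label, sym_text))
  children <- vector("list", natoms)
  next_label <- 0L

  # Pass 1: DFS spanning tree; leftover edges become ring closures.
  dfs <- function(a) {
    visited[a] <<- TRUE
    for (nb in adj[[a]]) {
      if (edge_used[[nb$edge]]) next
      if (!visited[[nb$to]]) {
        edge_used[[nb$edge]] <<- TRUE
        children[[a]] <<- c(children[[a]], list(nb))
        dfs(nb$to)
      } else {
        edge_used[[nb$edge]] <<- TRUE
        next_label <<- next_label + 1L
        lab <- if (next_label < 10L) as.character(next_label) else
          sprintf("%%%02d", next_label)
        bsym <- g$bonds[[nb$edge]]
        sym_text <- if (bsym$order != csm_default_bond(g, bsym$a, bsym$b)) bsym$order else ""
        ring_at[[a]] <<- c(ring_at[[a]], list(list(label = lab, sym = sym_text)))
        ring_at[[nb$to]] <<- c(ring_at[[nb$to]], list(list(label = lab, sym = "")))
      }
    }
  }
  dfs(1L)
  if (!all(visited)) {
    csm_abort("graph is not connected; components must be dot-separated upstream",
              "disconnected")
  }

  emit <- function(a) {
    out <- csm_format_anc(g$atoms[[a]])
    for (r in ring_at[[a]]) out <- paste0(out, r$sym, r$label)
    for (ann in g$atoms[[a]]$annotations) {
      out <- paste0(out, "{", csm_serialize_annotation(ann), "}")
    }
    kids <- children[[a]]
    if (length(kids)) {
      for (j in seq_along(kids)) {
        nb <- kids[[j]]
        e <- g$bonds[[nb$edge]]
        bsym <- if (e$order != csm_default_bond(g, e$a, e$b)) e$order else ""
        sub <- paste0(bsym, emit(nb$to))
        out <- if (j < length(kids)) paste0(out, "(", sub, ")") else paste0(out, sub)
      }
    }
    out
  }
  out <- emit(1L)
  for (ann in g$caa) out <- paste0(out, "{", csm_serialize_annotation(ann), "}")
  out
}

#' @export
print.csm_graph <- function(x, ...) {
  n_ann <- sum(vapply(x$atoms, function(a) length(a$annotations), 0L)) + length(x$caa)
  cat(sprintf("<molecular graph: %d atoms, %d bonds, %d annotations>\n",
              length(x$atoms), length(x$bonds), n_ann))
  cat(" ", csm_serialize_graph(x), "\n")
  invisible(x)
}
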