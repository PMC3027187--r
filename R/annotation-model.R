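# Annotation model: parse the text between a '{' and its matching '}' into a
# typed annotation object, classify it into one of the seven marker classes,
# parse its key=value dictionary (values may recursively be full notations)
# and resolve relative atomic-node pointers.
#
# Marker classes and their anchoring:
#   stereo  D/E/L/R/S/Z, one character, atom-anchored, no dictionary
#   unit    one boundary bond descriptor (- = # : & ~), atom-anchored
#   geam    group environment, bond symbol or '.' + {Y,R,X,|}, atom-anchored
#   mdam    molecular detail, '!' + {a,p,m,r,H,I}, atom-anchored
#   opam    operational, '+' + {R,X,Y,L,n,r}, atom-anchored
#   ssam    state and shape, two lower-case letters, component-anchored
#   miam    miscellaneous interest, other two-character marker,
#           component-anchored

CSM_STEREO_LETTERS <- c("D", "E", "L", "R", "S", "Z")
CSM_UNIT_DESCRIPTORS <- c("-", "=", "#", ":", "&", "~")
CSM_MDAM_SECOND <- c("a", "p", "m", "r", "H", "I")
CSM_OPAM_SECOND <- c("R", "X", "Y", "L", "n", "r")

csm_valid_geam_marker <- function(c1, c2) {
  if (c2 == "Y") return(c1 %in% c(CSM_UNIT_DESCRIPTORS))
  if (c2 %in% c("R", "X")) return(c1 == "-")
  if (c2 == "|") return(c1 %in% c("-", "~", "."))
  FALSE
}

#' Parse one curly-brace annotation
#'
#' Classifies the text found between one `{`/`}` pair into its marker class
#' (stereodescriptor, structural-unit boundary, group environment, molecular
#' detail, operational, state-and-shape or miscellaneous) and parses any
#' trailing dictionary of semicolon-separated `key=value` entries.
#'
#' Classification is by longest match: a lone upper-case D/E/L/R/S/Z is a
#' stereodescriptor and a lone bond symbol is a structural-unit boundary;
#' every other annotation must present a two-character marker. The marker
#' `". |"` sometimes typeset with a space is normalised to `.|`.
#'
#' @param interior The annotation text without its enclosing braces.
#' @return An object of class `csm_annotation` with fields `raw`,
#'   `marker_class`, `marker`, `entries` (list of dictionary entries) and
#'   `anchor_kind` (`"atom"` or `"component"`).
#' @examples
#' csm_parse_annotation("-|sfn=SiO2")
#' csm_parse_annotation("+rn=4")
#' @export
csm_parse_annotation <- function(interior) {
  raw <- interior
  # ". |" normalisation: a typeset space inside the surface-ion marker.
  if (identical(substr(interior, 1L, 3L), ". |")) {
    interior <- paste0(".|", substr(interior, 4L, nchar(interior)))
  }
  if (!nzchar(interior)) csm_abort("empty annotation", "bad_annotation")

  if (nchar(interior) == 1L) {
    if (interior %in% CSM_STEREO_LETTERS) {
      return(csm_annotation(raw, "stereo", interior, list(), "atom"))
    }
    if (interior %in% CSM_UNIT_DESCRIPTORS) {
      return(csm_annotation(raw, "unit", interior, list(), "atom"))
    }
    csm_abort(sprintf("invalid one-character annotation marker '%s'", interior),
              "bad_marker")
  }

  c1 <- substr(interior, 1L, 1L)
  c2 <- substr(interior, 2L, 2L)
  marker <- paste0(c1, c2)
  rest <- substr(interior, 3L, nchar(interior))
  reg <- csm_registries()

  if (c1 %in% c(CSM_UNIT_DESCRIPTORS, ".")) {
    if (!csm_valid_geam_marker(c1, c2)) {
      csm_abort(sprintf("invalid group-environment marker '%s'", marker), "bad_marker")
    }
    cls <- "geam"
  } else if (c1 == "!") {
    if (!c2 %in% CSM_MDAM_SECOND) {
      csm_abort(sprintf("invalid molecular-detail marker '%s'", marker), "bad_marker")
    }
    cls <- "mdam"
  } else if (c1 == "+") {
    if (!c2 %in% CSM_OPAM_SECOND) {
      csm_abort(sprintf("invalid operational marker '%s'", marker), "bad_marker")
    }
    cls <- "opam"
  } else if (grepl("^[a-z]{2}$", marker)) {
    cls <- "ssam"
    if (!marker %in% names(reg$ssam)) {
      csm_warn(sprintf("state-and-shape marker '%s' is not in the registry", marker),
               "unknown_ssam")
    }
  } else if (grepl("^[A-Za-z0-9]{2}$", marker)) {
    cls <- "miam"
    if (!marker %in% names(reg$miam)) {
      csm_warn(sprintf("miscellaneous marker '%s' is not in the registry", marker),
               "unknown_miam")
    }
  } else {
    csm_abort(sprintf("unrecognised annotation marker '%s'", marker), "bad_marker")
  }

  entries <- csm_parse_dictionary(rest)
  anchor <- if (cls %in% c("ssam", "miam")) "component" else "atom"
  csm_annotation(raw, cls, marker, entries, anchor)
}

csm_annotation <- function(raw, marker_class, marker, entries, anchor_kind) {
  structure(
    list(raw = raw, marker_class = marker_class, marker = marker,
         entries = entries, anchor_kind = anchor_kind),
    class = "csm_annotation"
  )
}

#' Parse an annotation dictionary
#'
#' Splits the post-marker remainder of an annotation into semicolon-separated
#' `key=value` entries. Splitting happens only at curly-brace depth zero, so
#' values carrying whole recursive notations (dictionary key `c`) stay
#' intact. Each entry is split at its first `=`; keys start with a letter or
#' `$` (customer-defined) followed by letters or underscores.
#'
#' Values are additionally typed where the form is recognised: signed
#' integers, integer ranges `lo-hi`, charge tokens (`+`, `-`, `2+`, ...) and,
#' for key `c`, a recursively parsed notation (in `parsed$value`).
#'
#' @param text The dictionary text (may be empty).
#' @return A list of entries, each a list with `key`, `customer`, `raw` and
#'   `parsed` (a list with a `type` field, or `NULL` for free text).
#' @examples
#' csm_parse_dictionary("sfn=SiO2;i=-2")
#' @export
csm_parse_dictionary <- function(text) {
  if (!nzchar(text)) return(list())
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[[i]] == "{") depth <- depth + 1L
    else if (chars[[i]] == "}") depth <- depth - 1L
    else if (chars[[i]] == ";" && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  entries <- vector("list", length(starts))
  seen <- character(0)
  reg <- csm_registries()
  for (k in seq_along(starts)) {
    part <- substr(text, starts[[k]], ends[[k]])
    eq <- regexpr("=", part, fixed = TRUE)
    if (eq < 1L) {
      csm_abort(sprintf("dictionary entry '%s' has no '='", part), "bad_dictionary")
    }
    key <- substr(part, 1L, eq - 1L)
    value <- substr(part, eq + 1L, nchar(part))
    if (!grepl("^[A-Za-z$][A-Za-z_]*$", key)) {
      csm_abort(sprintf("invalid dictionary key '%s'", key), "bad_dictionary")
    }
    if (key %in% seen) {
      csm_abort(sprintf("duplicate dictionary key '%s'", key), "bad_dictionary")
    }
    seen <- c(seen, key)
    customer <- startsWith(key, "$")
    if (!customer && !key %in% names(reg$dict_keys)) {
      csm_warn(sprintf("dictionary key '%s' is not in the registry", key),
               "unknown_key")
    }
    entries[[k]] <- list(key = key, customer = customer, raw = value,
                         parsed = csm_type_dict_value(key, value))
  }
  entries
}

# Best-effort typing of a dictionary value; unrecognised forms stay NULL
# (free text) and are round-tripped verbatim.
csm_type_dict_value <- function(key, value) {
  if (key == "c") {
    return(list(type = "notation", value = csm_parse(value)))
  }
  if (grepl("^[+-]?[0-9]+$", value)) {
    return(list(type = "int", value = as.integer(value)))
  }
  if (grepl("^[0-9]+-[0-9]+$", value)) {
    m <- strsplit(value, "-", fixed = TRUE)[[1]]
    return(list(type = "range", lo = as.integer(m[[1]]), hi = as.integer(m[[2]])))
  }
  if (grepl("^[0-9]*[+-]$", value)) {
    n <- sub("[+-]$", "", value)
    n <- if (nzchar(n)) as.integer(n) else 1L
    sign <- if (endsWith(value, "+")) 1L else -1L
    return(list(type = "charge", value = sign * n))
  }
  NULL
}

csm_dict_entry <- function(ann, key) {
  for (e in ann$entries) if (identical(e$key, key)) return(e)
  NULL
}

# Re-serialise a dictionary byte-for-byte from its entries.
csm_serialize_dictionary <- function(entries) {
  paste(vapply(entries, function(e) paste0(e$key, "=", e$raw), ""),
        collapse = ";")
}

csm_serialize_annotation <- function(ann) {
  ann$raw
}

#' Resolve a relative atomic-node pointer
#'
#' An annotation may carry an `i` dictionary entry whose signed integer value
#' points to another atomic node relative to the anchor, in order of
#' appearance: `i=-2` means "move left by two atomic nodes". The referenced
#' node must carry a group-environment annotation of the same marker (e.g.
#' the surface description that the pointer refers back to).
#'
#' @param ann A `csm_annotation` with an `i` entry.
#' @param graph A `csm_graph` (see [csm_parse_smiles()]).
#' @param anchor 1-based index of the atom the annotation is anchored to.
#' @return The 1-based index of the referenced atom.
#' @export
csm_resolve_pointer <- function(ann, graph, anchor) {
  e <- csm_dict_entry(ann, "i")
  if (is.null(e) || is.null(e$parsed) || e$parsed$type != "int") {
    csm_abort("annotation has no integer 'i' entry", "bad_pointer")
  }
  off <- e$parsed$value
  if (off == 0L) csm_abort("relative pointer offset must be nonzero", "bad_pointer")
  target <- anchor + off
  if (target < 1L || target > length(graph$atoms)) {
    csm_abort(sprintf("relative pointer resolves outside the graph (atom %d + %d)",
                      anchor - 1L, off), "bad_pointer")
  }
  anns <- graph$atoms[[target]]$annotations
  ok <- any(vapply(anns, function(a) {
    a$marker_class == "geam" && identical(a$marker, ann$marker) &&
      is.null(csm_dict_entry(a, "i"))
  }, TRUE))
  if (!ok) {
    csm_abort(sprintf("referenced atom %d carries no matching '%s' annotation",
                      target - 1L, ann$marker), "bad_pointer")
  }
  target
}

#' @export
print.csm_annotation <- function(x, ...) {
  cat(sprintf("<annotation {%s}: class %s, marker '%s', %d entr%s, %s-anchored>\n",
              x$raw, x$marker_class, x$marker, length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies", x$anchor_kind))
  invisible(x)
}
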