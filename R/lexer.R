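# Component lexer: brace- and bracket-aware scanning of a full notation into
# dot-separated top-level components, classification of each component's form
# and detachment of trailing multipliers.
#
# A '.' separates components only at nesting depth 0 of '{}', '[]' and '()'
# jointly: annotation dictionaries may carry entire recursive notations (dots
# included), so depth must be tracked across all three bracket kinds.

csm_check_text <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    csm_abort("notation must be a single character string", "input")
  }
  notation <- trimws(notation)
  if (!nzchar(notation)) {
    csm_abort("notation is empty", "empty_component")
  }
  if (grepl("[^\x20-\x7E]", notation)) {
    csm_abort("notation must be ASCII", "ascii")
  }
  if (grepl("[[:space:]]", notation)) {
    csm_abort("notation must not contain internal whitespace", "whitespace",
              offset = regexpr("[[:space:]]", notation) - 1L)
  }
  notation
}

# Positions (1-based) of top-level dots; errors on unbalanced brackets.
csm_top_level_dots <- function(chars) {
  dc <- ds <- dp <- 0L
  dots <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "{") dc <- dc + 1L
    else if (ch == "}") {
      dc <- dc - 1L
      if (dc < 0L) csm_abort("unbalanced '}'", "unbalanced", offset = i - 1L)
    } else if (ch == "[") ds <- ds + 1L
    else if (ch == "]") {
      ds <- ds - 1L
      if (ds < 0L) csm_abort("unbalanced ']'", "unbalanced", offset = i - 1L)
    } else if (ch == "(") dp <- dp + 1L
    else if (ch == ")") {
      dp <- dp - 1L
      if (dp < 0L) csm_abort("unbalanced ')'", "unbalanced", offset = i - 1L)
    } else if (ch == "." && dc == 0L && ds == 0L && dp == 0L) {
      dots <- c(dots, i)
    }
  }
  if (dc > 0L) csm_abort("unclosed '{'", "unbalanced", offset = length(chars))
  if (ds > 0L) csm_abort("unclosed '['", "unbalanced", offset = length(chars))
  if (dp > 0L) csm_abort("unclosed '('", "unbalanced", offset = length(chars))
  dots
}

# Detach a trailing top-level '{digits}' multiplier block. '{1}' and '{0}'
# are errors: a multiplier is an integer greater than one by definition.
csm_detach_multiplier <- function(text) {
  if (!endsWith(text, "}")) {
    return(list(text = text, multiplier = 1L))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  open <- NA_integer_
  for (i in rev(seq_along(chars))) {
    if (chars[[i]] == "}") depth <- depth + 1L
    else if (chars[[i]] == "{") {
      depth <- depth - 1L
      if (depth == 0L) { open <- i; break }
    }
  }
  if (is.na(open)) csm_abort("unbalanced '}'", "unbalanced")
  interior <- substr(text, open + 1L, nchar(text) - 1L)
  if (!grepl("^[0-9]+$", interior)) {
    return(list(text = text, multiplier = 1L))
  }
  n <- suppressWarnings(as.integer(interior))
  if (is.na(n) || n < 2L) {
    csm_abort(sprintf("multiplier {%s} is invalid: must be an integer greater than one", interior),
              "bad_multiplier", offset = open - 1L)
  }
  rest <- substr(text, 1L, open - 1L)
  if (!nzchar(rest)) {
    csm_abort("multiplier with no component notation", "bad_multiplier")
  }
  list(text = rest, multiplier = n)
}

csm_classify_text <- function(text) {
  if (!startsWith(text, "{")) return("smiles")
  second <- substr(text, 2L, 2L)
  if (second == "*") return("sfn")
  if (second == "/") return("composite")
  if (grepl("^[A-Za-z$]$", second)) return("alias")
  csm_abort(sprintf("malformed special-format component: '{' followed by '%s'", second),
            "malformed_special", offset = 1L)
}

# A special-format component must be exactly one '{...}' block (the block
# that opens at position 1 must close at the last character).
csm_check_special_span <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[[i]] == "{") depth <- depth + 1L
    else if (chars[[i]] == "}") {
      depth <- depth - 1L
      if (depth == 0L) {
        if (i != length(chars)) {
          csm_abort("special-format component has trailing characters after '}'",
                    "malformed_special", offset = i)
        }
        return(invisible(TRUE))
      }
    }
  }
  csm_abort("unclosed special-format component", "unbalanced")
}

# Internal lexer: list of raw components, each
# list(text, form, multiplier, src).
csm_lex <- function(notation) {
  notation <- csm_check_text(notation)
  chars <- strsplit(notation, "", fixed = TRUE)[[1]]
  dots <- csm_top_level_dots(chars)
  starts <- c(1L, dots + 1L)
  ends <- c(dots - 1L, length(chars))
  comps <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    src <- substr(notation, starts[[k]], ends[[k]])
    if (!nzchar(src)) {
      csm_abort("empty component (leading, trailing or doubled dot)",
                "empty_component", offset = starts[[k]] - 1L)
    }
    det <- csm_detach_multiplier(src)
    form <- csm_classify_text(det$text)
    if (form != "smiles") csm_check_special_span(det$text)
    if (form == "composite") {
      if (length(starts) > 1L) {
        csm_abort("a composite notation must be unary (the only component)",
                  "nonunary_composite")
      }
      if (det$multiplier > 1L) {
        csm_abort("a composite notation cannot carry a multiplier",
                  "bad_multiplier")
      }
    }
    comps[[k]] <- list(text = det$text, form = form,
                       multiplier = as.integer(det$multiplier), src = src)
  }
  comps
}

#' Split a notation into its top-level components
#'
#' Scans a chemical line notation and splits it on dots that occur at nesting
#' depth zero of curly braces, square brackets and parentheses, so that dots
#' inside annotation dictionaries, square-bracket atomic codes or alias names
#' never split. Each component's trailing `{n}` multiplier (an integer
#' greater than one) is detached and reported separately.
#'
#' @param notation A single notation string.
#' @return A tibble with one row per component and columns `component` (the
#'   component notation without its multiplier), `form` (one of `"smiles"`,
#'   `"alias"`, `"sfn"`, `"composite"`) and `multiplier` (integer, `1` when
#'   no multiplier block was present).
#' @examples
#' csm_split_components("[Co+2].[O-]N(=O)=O{2}.O{6}")
#' @export
csm_split_components <- function(notation) {
  comps <- csm_lex(notation)
  tibble::tibble(
    component  = vapply(comps, `[[`, "", "text"),
    form       = vapply(comps, `[[`, "", "form"),
    multiplier = vapply(comps, `[[`, 1L, "multiplier")
  )
}
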