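# Top-level entry points: parse a full notation into an ordered list of
# parsed components, and serialise a parsed notation back to a string.

#' Parse a chemical line notation
#'
#' Splits the notation into dot-separated components, classifies each and
#' parses it with the appropriate engine: SMILES-form components become
#' molecular graphs carrying their annotations, `{*...}` components become
#' stoichiometric compositions, `{alias}` components become alias
#' references (optionally resolved against look-up tables) and `{/...}`
#' composites become ordered constituent lists.
#'
#' @param notation A single notation string.
#' @param aliases Optional list of alias tables ([csm_read_aliases()]); when
#'   supplied, alias components are resolved and the parsed replacement is
#'   attached as `resolved` on the alias content.
#' @return An object of class `csm_notation`: a list with `components`
#'   (each a list of `text`, `form`, `multiplier`, `content`) and `src`.
#' @examples
#' x <- csm_parse("[Co+2].[O-]N(=O)=O{2}.O{6}")
#' length(x$components)
#' @export
csm_parse <- function(notation, aliases = NULL) {
  rcs <- csm_lex(notation)
  comps <- lapply(rcs, function(rc) {
    interior <- substr(rc$text, 2L, nchar(rc$text) - 1L)
    content <- switch(rc$form,
      smiles = csm_parse_smiles(rc$text),
      sfn = csm_parse_sfn(substr(interior, 2L, nchar(interior))),
      alias = {
        ref <- csm_parse_alias(interior)
        if (!is.null(aliases)) {
          rep_rc <- csm_resolve_alias(ref, aliases)
          ref$resolved <- switch(rep_rc$form,
            smiles = csm_parse_smiles(rep_rc$text),
            sfn = csm_parse_sfn(substr(rep_rc$text, 3L, nchar(rep_rc$text) - 1L)),
            rep_rc
          )
        }
        ref
      },
      composite = csm_parse_composite(interior)
    )
    list(text = rc$text, form = rc$form, multiplier = rc$multiplier,
         content = content)
  })
  structure(list(components = comps, src = trimws(notation)),
            class = "csm_notation")
}

#' Serialise a parsed notation
#'
#' Reassembles the dot-separated notation, re-appending `{n}` multipliers.
#' Components still carrying their source text round-trip byte-identically;
#' programmatically built graphs are written by the graph serialiser.
#'
#' @param x A `csm_notation` (or a string, returned unchanged after a
#'   parse check).
#' @return A notation string.
#' @examples
#' csm_serialize(csm_parse("{*Cr23C6}"))
#' @export
csm_serialize <- function(x) {
  if (is.character(x)) x <- csm_parse(x)
  if (!inherits(x, "csm_notation")) {
    csm_abort("csm_serialize expects a csm_notation", "input")
  }
  parts <- vapply(x$components, function(comp) {
    text <- comp$text
    if (is.null(text)) {
      text <- switch(comp$form,
        smiles = csm_serialize_graph(comp$content),
        sfn = paste0("{*", csm_serialize_sfn(comp$content), "}"),
        alias = paste0("{", comp$content$name, "}"),
        composite = paste0("{", csm_serialize_composite(comp$content), "}")
      )
    }
    if (comp$multiplier > 1L) paste0(text, "{", comp$multiplier, "}") else text
  }, "")
  paste(parts, collapse = ".")
}

#' Validate a notation
#'
#' @param notation A notation string.
#' @param aliases Optional alias tables; when supplied, alias components
#'   must also resolve.
#' @return `TRUE` invisibly on success; signals a classed `csm_error`
#'   condition describing the first violation otherwise.
#' @export
csm_validate <- function(notation, aliases = NULL) {
  csm_parse(notation, aliases = aliases)
  invisible(TRUE)
}

#' Parse a batch of notations into a tibble
#'
#' @param notations Character vector of notations.
#' @param aliases Optional alias tables.
#' @return A tibble with columns `notation`, `ok`, `n_components`, `forms`
#'   (comma-separated), `error` (message or `NA`) and `parsed`
#'   (list-column of `csm_notation` or `NULL`).
#' @export
csm_parse_batch <- function(notations, aliases = NULL) {
  rows <- lapply(notations, function(s) {
    res <- tryCatch(csm_parse(s, aliases = aliases), csm_error = function(e) e)
    if (inherits(res, "csm_error")) {
      list(notation = s, ok = FALSE, n_components = NA_integer_,
           forms = NA_character_, error = conditionMessage(res), parsed = list(NULL))
    } else {
      list(notation = s, ok = TRUE, n_components = length(res$components),
           forms = paste(vapply(res$components, `[[`, "", "form"), collapse = ","),
           error = NA_character_, parsed = list(res))
    }
  })
  tibble::tibble(
    notation = vapply(rows, `[[`, "", "notation"),
    ok = vapply(rows, `[[`, TRUE, "ok"),
    n_components = vapply(rows, `[[`, 1L, "n_components"),
    forms = vapply(rows, `[[`, "", "forms"),
    error = vapply(rows, `[[`, "", "error"),
    parsed = lapply(rows, function(r) r$parsed[[1]])
  )
}

#' @export
print.csm_notation <- function(x, ...) {
  cat(sprintf("<notation: %d component%s>\n", length(x$components),
              if (length(x$components) == 1L) "" else "s"))
  for (comp in x$components) {
    mult <- if (comp$multiplier > 1L) sprintf(" x%d", comp$multiplier) else ""
    cat(sprintf("  [%s]%s %s\n", comp$form, mult, comp$text))
  }
  invisible(x)
}

#' @export
format.csm_notation <- function(x, ...) csm_serialize(x)
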