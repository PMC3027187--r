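# Alias and composite special forms.
#
# An alias is a curly-braced short name standing for one component notation;
# a `$` prefix marks customer-defined aliases, which are resolved against a
# user-supplied look-up table (predefined aliases resolve against the
# internal seed table). A composite `{/c1/c2/.../cn}` lists constituents in
# interfacial contact and is always the entire notation.

#' Parse an alias reference
#'
#' @param text Alias name (the text between the braces), e.g. `"bmim(1+)"`
#'   or `"$myCation"`.
#' @return An object of class `csm_alias` with `name`, `customer` (`TRUE`
#'   for `$`-prefixed names) and `charge` — the signed charge declared by a
#'   terminal `(n+)`/`(n-)` suffix in the name, or `NA` when absent.
#' @examples
#' csm_parse_alias("bmim(1+)")$charge
#' @export
csm_parse_alias <- function(text) {
  if (!grepl("^[A-Za-z$][A-Za-z0-9_+()-]*$", text)) {
    csm_abort(sprintf("invalid alias name '%s'", text), "bad_alias")
  }
  charge <- NA_integer_
  m <- regmatches(text, regexpr("\\(([0-9]+)([+-])\\)$", text))
  if (length(m)) {
    mag <- as.integer(gsub("[^0-9]", "", m))
    charge <- if (grepl("\\+\\)$", m)) mag else -mag
  }
  structure(
    list(name = text, customer = startsWith(text, "$"), charge = charge),
    class = "csm_alias"
  )
}

#' Load an alias look-up table
#'
#' Reads a plain-text alias dictionary: one `alias<TAB>replacement-notation`
#' entry per line, `#` comment lines and blank lines ignored. Every
#' replacement must lex as exactly one non-composite component; duplicate
#' aliases within one file are an error.
#'
#' @param path File path.
#' @param scope `"customer"` or `"predefined"`; customer tables are searched
#'   first during resolution, and only they may satisfy `$`-prefixed
#'   references.
#' @return An object of class `csm_alias_table`.
#' @export
csm_read_aliases <- function(path, scope = c("customer", "predefined")) {
  scope <- match.arg(scope)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  entries <- character(0)
  for (ln in which(keep)) {
    parts <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[[1]]) || !nzchar(parts[[2]])) {
      csm_abort(sprintf("malformed alias line %d: expected 'alias<TAB>notation'", ln),
                "bad_alias_table")
    }
    csm_parse_alias(parts[[1]])
    comps <- csm_lex(parts[[2]])
    if (length(comps) != 1L || comps[[1]]$form == "composite") {
      csm_abort(sprintf("alias replacement on line %d must be a single non-composite component", ln),
                "bad_alias_table")
    }
    if (parts[[1]] %in% names(entries)) {
      csm_abort(sprintf("duplicate alias '%s' (line %d)", parts[[1]], ln),
                "bad_alias_table")
    }
    entries[[parts[[1]]]] <- parts[[2]]
  }
  structure(list(entries = entries, scope = scope), class = "csm_alias_table")
}

#' The packaged seed table of predefined aliases
#'
#' A small editable seed (common ionic-liquid cations and anions); the full
#' predefined registry of the language is an external resource, so any
#' lookup that falls through all tables is an error rather than a warning.
#'
#' @return A list containing one predefined `csm_alias_table`.
#' @export
csm_default_aliases <- function() {
  path <- system.file("extdata", "aliases_predefined.tsv", package = "curlysmiles")
  list(csm_read_aliases(path, scope = "predefined"))
}

#' Resolve an alias to its replacement component
#'
#' Looks the alias name up (with any charge suffix included in the key)
#' across the supplied tables, customer-scope tables first. Replacements
#' that are themselves aliases are resolved transitively; cycles are
#' detected and reported.
#'
#' @param ref A `csm_alias` or an alias name string.
#' @param tables A list of `csm_alias_table` objects (see
#'   [csm_read_aliases()], [csm_default_aliases()]).
#' @return The replacement raw component: a list with `text`, `form`,
#'   `multiplier`.
#' @export
csm_resolve_alias <- function(ref, tables = csm_default_aliases(), .visited = character(0)) {
  if (is.character(ref)) ref <- csm_parse_alias(ref)
  if (ref$name %in% .visited) {
    csm_abort(sprintf("alias cycle detected at '%s'", ref$name), "alias_cycle")
  }
  if (inherits(tables, "csm_alias_table")) tables <- list(tables)
  scopes <- vapply(tables, `[[`, "", "scope")
  search <- c(tables[scopes == "customer"], tables[scopes == "predefined"])
  if (ref$customer && !any(scopes == "customer")) {
    csm_abort(sprintf("customer-defined alias '%s' requires a customer look-up table", ref$name),
              "unknown_alias")
  }
  if (ref$customer) search <- tables[scopes == "customer"]
  for (tab in search) {
    if (ref$name %in% names(tab$entries)) {
      comp <- csm_lex(tab$entries[[ref$name]])[[1]]
      if (comp$form == "alias") {
        inner <- csm_parse_alias(substr(comp$text, 2L, nchar(comp$text) - 1L))
        return(csm_resolve_alias(inner, tables, .visited = c(.visited, ref$name)))
      }
      return(comp)
    }
  }
  csm_abort(sprintf("unknown alias '%s'", ref$name), "unknown_alias")
}

#' Parse a composite notation
#'
#' Parses the interior of a `{/c1/c2/.../cn}` component: the ordered list of
#' constituents in interfacial contact. Each constituent is either an
#' `{*...}` stoichiometric formula or an (annotated) SMILES component;
#' slashes split only at brace depth zero. A composite needs at least two
#' constituents and order is preserved (interface order is meaningful).
#'
#' @param text The composite interior, starting with `/`.
#' @return An object of class `csm_composite` with `constituents`, a list of
#'   elements each holding `form` (`"sfn"` or `"smiles"`), `content` (a
#'   `csm_sfn` or `csm_graph`) and `src`.
#' @export
csm_parse_composite <- function(text) {
  if (!startsWith(text, "/")) {
    csm_abort("composite interior must start with '/'", "bad_composite")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  dc <- ds <- dp <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "{") dc <- dc + 1L else if (ch == "}") dc <- dc - 1L
    else if (ch == "[") ds <- ds + 1L else if (ch == "]") ds <- ds - 1L
    else if (ch == "(") dp <- dp + 1L else if (ch == ")") dp <- dp - 1L
    else if (ch == "/" && dc == 0L && ds == 0L && dp == 0L) cuts <- c(cuts, i)
  }
  starts <- cuts + 1L
  ends <- c(cuts[-1L] - 1L, length(chars))
  pieces <- substring(text, starts, ends)
  if (any(!nzchar(pieces))) csm_abort("empty composite constituent", "bad_composite")
  if (length(pieces) < 2L) {
    csm_abort("a composite requires at least two constituents", "bad_composite")
  }
  constituents <- lapply(pieces, function(p) {
    if (startsWith(p, "{*")) {
      if (!endsWith(p, "}")) csm_abort("malformed constituent formula", "bad_composite")
      list(form = "sfn", content = csm_parse_sfn(substr(p, 3L, nchar(p) - 1L)), src = p)
    } else if (startsWith(p, "{")) {
      csm_abort("composite constituents must be formulas ({*...}) or SMILES components",
                "bad_composite")
    } else {
      list(form = "smiles", content = csm_parse_smiles(p), src = p)
    }
  })
  structure(list(constituents = constituents, src = text), class = "csm_composite")
}

csm_serialize_composite <- function(x) {
  paste0(vapply(x$constituents, function(co) paste0("/", co$src), ""),
         collapse = "")
}

#' @export
print.csm_alias <- function(x, ...) {
  cat(sprintf("<alias '%s'%s%s>\n", x$name,
              if (x$customer) ", customer-defined" else "",
              if (!is.na(x$charge)) sprintf(", declared charge %+d", x$charge) else ""))
  invisible(x)
}

#' @export
print.csm_composite <- function(x, ...) {
  cat(sprintf("<composite: %d constituents in interfacial contact>\n",
              length(x$constituents)))
  for (co in x$constituents) cat(sprintf("  [%s] %s\n", co$form, co$src))
  invisible(x)
}
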