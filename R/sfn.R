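# Stoichiometric formula notation (SFN): composition-based encoding for
# materials without a discrete finite connectivity pattern. Grammar:
# greedy multi-letter element tokens (two-letter symbols before one-letter),
# '^' isotope labels preceding a symbol, counts directly following a symbol
# or a ')' group close, nestable '(...)' groups, and a single terminal
# '(n+)'/'(n-)' charge.

#' Parse a stoichiometric formula notation
#'
#' Parses the interior of an `{*...}` component (or a bare formula such as a
#' dictionary value `sfn=SiO2`) into a nested group tree and a flattened
#' element-to-count map. Isotope-labelled species are counted separately
#' from the unlabelled element (`^13C` is distinct from `C`); group counts
#' multiply through all nesting levels; a single terminal `(n+)`/`(n-)`
#' suffix gives the net charge.
#'
#' @param text Formula text, without the `{*` `}` wrapper.
#' @return An object of class `csm_sfn` with fields `root` (the group tree),
#'   `flattened` (named integer vector of species counts), `charge`
#'   (integer) and `src`.
#' @examples
#' csm_parse_sfn("Cu3(CO3)2(OH)2")
#' csm_parse_sfn("Bi5(4+)")$charge
#' @export
csm_parse_sfn <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    csm_abort("empty stoichiometric formula", "bad_sfn")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L
  charge <- 0L
  charge_seen <- FALSE

  read_count <- function() {
    start <- pos
    while (pos <= n && grepl("^[0-9]$", chars[[pos]])) pos <<- pos + 1L
    if (pos == start) return(1L)
    cnt <- as.integer(substr(text, start, pos - 1L))
    if (cnt == 0L) {
      csm_abort("zero stoichiometric count", "bad_sfn", offset = start - 1L)
    }
    cnt
  }

  parse_group <- function(depth) {
    items <- list()
    while (pos <= n) {
      ch <- chars[[pos]]
      if (ch == ")") {
        if (depth == 0L) {
          csm_abort("unbalanced ')' in formula", "bad_sfn", offset = pos - 1L)
        }
        return(items)
      }
      if (charge_seen) {
        csm_abort("charge suffix must terminate the formula", "bad_sfn",
                  offset = pos - 1L)
      }
      if (ch == "(") {
        open <- pos
        close <- csm_match_paren(chars, pos)
        inner <- substr(text, open + 1L, close - 1L)
        if (grepl("^[0-9]+[+-]$", inner)) {
          if (depth > 0L) {
            csm_abort("charge suffix inside a nested group", "bad_sfn",
                      offset = open - 1L)
          }
          mag <- as.integer(sub("[+-]$", "", inner))
          if (mag < 1L) csm_abort("charge magnitude must be >= 1", "bad_sfn")
          charge <<- if (endsWith(inner, "+")) mag else -mag
          charge_seen <<- TRUE
          pos <<- close + 1L
          next
        }
        pos <<- open + 1L
        sub <- parse_group(depth + 1L)
        if (pos > n || chars[[pos]] != ")") {
          csm_abort("unclosed '(' in formula", "bad_sfn", offset = open - 1L)
        }
        if (!length(sub)) {
          csm_abort("empty group in formula", "bad_sfn", offset = open - 1L)
        }
        pos <<- pos + 1L
        cnt <- read_count()
        items[[length(items) + 1L]] <- list(kind = "group", items = sub, count = cnt)
        next
      }
      isotope <- NA_integer_
      if (ch == "^") {
        pos <<- pos + 1L
        start <- pos
        while (pos <= n && grepl("^[0-9]$", chars[[pos]])) pos <<- pos + 1L
        if (pos == start) {
          csm_abort("dangling '^' isotope label", "bad_sfn", offset = start - 2L)
        }
        isotope <- as.integer(substr(text, start, pos - 1L))
        if (pos > n) csm_abort("isotope label with no element", "bad_sfn")
        ch <- chars[[pos]]
      }
      if (grepl("^[A-Z]$", ch)) {
        sym <- ch
        if (pos < n && grepl("^[a-z]$", chars[[pos + 1L]]) &&
            csm_is_element(paste0(ch, chars[[pos + 1L]]))) {
          sym <- paste0(ch, chars[[pos + 1L]])
        }
        if (!csm_is_element(sym)) {
          csm_abort(sprintf("unknown element symbol '%s'", sym), "unknown_element",
                    offset = pos - 1L)
        }
        pos <<- pos + nchar(sym)
        cnt <- read_count()
        items[[length(items) + 1L]] <- list(kind = "element", symbol = sym,
                                            isotope = isotope, count = cnt)
        next
      }
      csm_abort(sprintf("unexpected character '%s' in formula", ch), "bad_sfn",
                offset = pos - 1L)
    }
    items
  }

  items <- parse_group(0L)
  if (!length(items) && charge == 0L) csm_abort("empty formula", "bad_sfn")
  root <- list(kind = "group", items = items, count = 1L)
  structure(
    list(root = root, flattened = csm_flatten_sfn(root), charge = charge,
         src = text),
    class = "csm_sfn"
  )
}

csm_match_paren <- function(chars, open) {
  depth <- 0L
  for (i in open:length(chars)) {
    if (chars[[i]] == "(") depth <- depth + 1L
    else if (chars[[i]] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  csm_abort("unclosed '(' in formula", "bad_sfn", offset = open - 1L)
}

csm_species_key <- function(symbol, isotope) {
  if (is.na(isotope)) symbol else paste0("^", isotope, symbol)
}

# Recursive product-sum flattening: flatten(group with count k) equals
# k * flatten(group with count 1).
csm_flatten_sfn <- function(node) {
  totals <- integer(0)
  add <- function(key, cnt) {
    totals[key] <<- (if (key %in% names(totals)) totals[[key]] else 0L) + cnt
  }
  walk <- function(node, mult) {
    for (it in node$items) {
      if (it$kind == "element") {
        add(csm_species_key(it$symbol, it$isotope), it$count * mult)
      } else {
        walk(it, mult * it$count)
      }
    }
  }
  walk(node, node$count)
  totals
}

#' Serialise a stoichiometric composition
#'
#' Writes the nested group tree back to formula text in source order;
#' explicit counts of one are omitted, matching the input grammar, so
#' `csm_parse_sfn(csm_serialize_sfn(x))` reproduces the tree, flattened map
#' and charge.
#'
#' @param comp A `csm_sfn` object.
#' @return A single formula string (without the `{*` `}` wrapper).
#' @export
csm_serialize_sfn <- function(comp) {
  emit <- function(node) {
    paste(vapply(node$items, function(it) {
      cnt <- if (it$count > 1L) as.character(it$count) else ""
      if (it$kind == "element") {
        iso <- if (!is.na(it$isotope)) paste0("^", it$isotope) else ""
        paste0(iso, it$symbol, cnt)
      } else {
        paste0("(", emit(it), ")", cnt)
      }
    }, ""), collapse = "")
  }
  out <- emit(comp$root)
  if (comp$charge != 0L) {
    out <- paste0(out, "(", abs(comp$charge),
                  if (comp$charge > 0L) "+" else "-", ")")
  }
  out
}

#' Compare two stoichiometric compositions
#'
#' Order- and grouping-insensitive equality: two compositions match when
#' their flattened species maps and net charges are equal, so notations
#' written with symbols in any order (the grammar allows repeats and
#' arbitrary order) compare equal.
#'
#' @param a,b `csm_sfn` objects or formula strings.
#' @return `TRUE` or `FALSE`.
#' @examples
#' csm_compare_sfn("C6Cr23", "Cr23C6")
#' @export
csm_compare_sfn <- function(a, b) {
  if (is.character(a)) a <- csm_parse_sfn(a)
  if (is.character(b)) b <- csm_parse_sfn(b)
  fa <- a$flattened[order(names(a$flattened))]
  fb <- b$flattened[order(names(b$flattened))]
  identical(as.list(fa), as.list(fb)) && a$charge == b$charge
}

#' @export
print.csm_sfn <- function(x, ...) {
  cat(sprintf("<stoichiometric composition: %s>\n", csm_serialize_sfn(x)))
  counts <- x$flattened
  for (k in names(counts)) cat(sprintf("  %-6s %d\n", k, counts[[k]]))
  if (x$charge != 0L) cat(sprintf("  charge %+d\n", x$charge))
  invisible(x)
}
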