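# Deterministic generator of valid (and deliberately corrupted) notations
# with known ground truth, for property-style testing. Generation limits
# are kept small (<= 20 atoms per component, <= 5 components, nesting <= 3)
# so that brute-force oracles stay trivial. Chemical sensibility is not a
# goal: the generator exercises the grammar, not chemistry.

csm_gen_bare_atom <- function() {
  sample(c("C", "C", "C", "N", "O", "S", "P", "F", "Cl", "Br"), 1L)
}

csm_gen_sqc_atom <- function() {
  sample(c("[NH4+]", "[O-]", "[CH3]", "[13C]", "[Co+2]", "[SiH2]", "[Fe+3]"), 1L)
}

csm_gen_atom <- function() {
  if (stats::runif(1) < 0.2) csm_gen_sqc_atom() else csm_gen_bare_atom()
}

# Plain component built atom-wise; returns tokens (one per atom, rings
# merged into their atom token) plus exact atom/bond counts.
csm_gen_plain <- function() {
  target <- sample(3:14, 1L)
  tokens <- csm_gen_atom()
  atoms <- 1L
  bonds <- 0L
  while (atoms < target) {
    r <- stats::runif(1)
    if (r < 0.12 && atoms >= 1L && target - atoms >= 3L) {
      rs <- sample(3:6, 1L)
      rs <- min(rs, target - atoms)
      if (rs < 3L) next
      mid <- paste(sample(c("C", "N", "O"), rs - 2L, replace = TRUE), collapse = "")
      tokens <- c(tokens, "C9", strsplit(mid, "")[[1]], "C9")
      atoms <- atoms + rs
      bonds <- bonds + rs + 1L     # rs ring bonds + 1 attachment bond
    } else if (r < 0.32) {
      b <- sample(c("", "", "", "="), 1L)
      tokens <- c(tokens, paste0("(", b, csm_gen_atom(), ")"))
      atoms <- atoms + 1L
      bonds <- bonds + 1L
    } else {
      b <- sample(c("", "", "", "", "=", "#"), 1L)
      tokens <- c(tokens, paste0(b, csm_gen_atom()))
      atoms <- atoms + 1L
      bonds <- bonds + 1L
    }
  }
  list(tokens = tokens, atoms = atoms, bonds = bonds)
}

csm_gen_sfn_tree <- function(depth = 0L) {
  n_items <- sample(1:4, 1L)
  text <- ""
  flat <- integer(0)
  add <- function(key, n) {
    flat[key] <<- (if (key %in% names(flat)) flat[[key]] else 0L) + n
  }
  pool <- c("C", "O", "Si", "Al", "Fe", "Cu", "Zr", "Ti", "K", "Na", "S",
            "N", "Cr", "Au", "Bi", "P", "Mg", "Ca", "Zn", "Mn")
  for (j in seq_len(n_items)) {
    if (depth < 2L && stats::runif(1) < 0.25) {
      sub <- csm_gen_sfn_tree(depth + 1L)
      cnt <- sample(1:4, 1L)
      text <- paste0(text, "(", sub$text, ")", if (cnt > 1L) cnt else "")
      for (k in names(sub$flat)) add(k, sub$flat[[k]] * cnt)
    } else {
      sym <- sample(pool, 1L)
      iso <- ""
      key <- sym
      if (sym == "C" && stats::runif(1) < 0.15) {
        iso <- "^13"
        key <- "^13C"
      }
      cnt <- sample(1:30, 1L)
      text <- paste0(text, iso, sym, if (cnt > 1L) cnt else "")
      add(key, cnt)
    }
  }
  list(text = text, flat = flat)
}

#' Generate a random notation with known ground truth
#'
#' Deterministic for a given `(seed, profile)` pair. Profiles:
#' `"plain"` (one SMILES component), `"annotated"` (SMILES with planted
#' annotations, including a planted relative-pointer pair), `"sfn"` (one
#' stoichiometric formula), `"composite"` and `"mixed"` (several components
#' with multipliers).
#'
#' @param seed Integer seed.
#' @param profile One of `"plain"`, `"annotated"`, `"sfn"`, `"composite"`,
#'   `"mixed"`.
#' @return A list with `notation` and `truth`; the truth record is computed
#'   by generator bookkeeping, independently of the parser, and carries
#'   (depending on profile) `atoms`, `bonds`, `flattened`, `charge`,
#'   `n_components`, `multipliers`, `n_constituents`, `annotations`,
#'   `pointer` (a list with planted `anchor` and `target`, 1-based).
#' @export
csm_generate <- function(seed,
                         profile = c("plain", "annotated", "sfn", "composite", "mixed")) {
  profile <- match.arg(profile)
  withr::with_seed(seed, csm_generate_impl(profile))
}

csm_generate_impl <- function(profile) {
  switch(profile,
    plain = {
      p <- csm_gen_plain()
      list(notation = paste(p$tokens, collapse = ""),
           truth = list(atoms = p$atoms, bonds = p$bonds))
    },
    annotated = {
      p <- csm_gen_plain()
      tokens <- p$tokens
      anns <- list()
      n_atoms_tok <- length(tokens)
      # each token holds exactly one atom (branch tokens included), so the
      # token index equals the atom appearance index
      append_ann <- function(tok, a) {
        if (endsWith(tok, ")")) {
          paste0(substr(tok, 1L, nchar(tok) - 1L), a, ")")
        } else {
          paste0(tok, a)
        }
      }
      for (idx in sample(n_atoms_tok, min(2L, n_atoms_tok))) {
        a <- sample(c("{R}", "{S}", "{-}", "{!re=+}", "{+rn=3}"), 1L)
        tokens[[idx]] <- append_ann(tokens[[idx]], a)
        anns[[length(anns) + 1L]] <- list(token = idx, text = a)
      }
      pointer <- NULL
      if (n_atoms_tok >= 3L) {
        pair <- sort(sample(n_atoms_tok, 2L))
        off <- pair[[1]] - pair[[2]]
        tokens[[pair[[1]]]] <- append_ann(tokens[[pair[[1]]]], "{-|sfn=TiO2}")
        tokens[[pair[[2]]]] <- append_ann(tokens[[pair[[2]]]],
                                          paste0("{-|i=", off, "}"))
        pointer <- list(anchor = pair[[2]], target = pair[[1]])
      }
      list(notation = paste(tokens, collapse = ""),
           truth = list(atoms = p$atoms, bonds = p$bonds,
                        annotations = anns, pointer = pointer))
    },
    sfn = {
      tr <- csm_gen_sfn_tree()
      charge <- 0L
      text <- tr$text
      if (stats::runif(1) < 0.3) {
        mag <- sample(1:4, 1L)
        sgn <- sample(c("+", "-"), 1L)
        text <- paste0(text, "(", mag, sgn, ")")
        charge <- if (sgn == "+") mag else -mag
      }
      list(notation = paste0("{*", text, "}"),
           truth = list(flattened = tr$flat, charge = charge))
    },
    composite = {
      n <- sample(2:3, 1L)
      pieces <- character(n)
      forms <- character(n)
      for (j in seq_len(n)) {
        if (stats::runif(1) < 0.5) {
          pieces[[j]] <- paste0("{*", csm_gen_sfn_tree()$text, "}")
          forms[[j]] <- "sfn"
        } else {
          pieces[[j]] <- paste(csm_gen_plain()$tokens, collapse = "")
          forms[[j]] <- "smiles"
        }
      }
      list(notation = paste0("{", paste0("/", pieces, collapse = ""), "}"),
           truth = list(n_constituents = n, forms = forms))
    },
    mixed = {
      n <- sample(1:5, 1L)
      comps <- character(n)
      mult <- integer(n)
      for (j in seq_len(n)) {
        comps[[j]] <- switch(sample(3, 1L),
          paste(csm_gen_plain()$tokens, collapse = ""),
          paste0("{*", csm_gen_sfn_tree()$text, "}"),
          sample(c("{bmim(1+)}", "{NTf2(1-)}", "{$myCation}"), 1L)
        )
        mult[[j]] <- sample(c(1L, 1L, 1L, 2L, 3L, 6L), 1L)
        if (mult[[j]] > 1L) comps[[j]] <- paste0(comps[[j]], "{", mult[[j]], "}")
      }
      list(notation = paste(comps, collapse = "."),
           truth = list(n_components = n, multipliers = mult,
                        total_multiplicity = sum(mult)))
    }
  )
}

#' Corrupt a valid notation into a known error class
#'
#' Applies one random corruption — unbalancing a brace, inserting internal
#' whitespace, inserting a stereo glyph into a SMILES component, appending a
#' `{1}` multiplier, or making a composite non-unary — and records the
#' condition class the parser must signal for it.
#'
#' @param notation A valid notation string.
#' @param seed Integer seed.
#' @return A list with `notation` (the corrupted string) and `error_class`
#'   (the expected condition class, e.g. `"csm_error_stereo_glyph"`).
#' @export
csm_mutate_invalid <- function(notation, seed) {
  withr::with_seed(seed, {
    comps <- csm_lex(notation)
    forms <- vapply(comps, `[[`, "", "form")
    choices <- c("unbalanced", "bad_multiplier")
    if (nchar(notation) > 1L) choices <- c(choices, "whitespace")
    if (any(forms == "smiles")) choices <- c(choices, "stereo_glyph")
    if (any(forms == "composite")) choices <- c(choices, "nonunary_composite")
    kind <- sample(choices, 1L)
    mutated <- switch(kind,
      unbalanced = {
        if (grepl("}", notation, fixed = TRUE)) {
          sub("\\}([^}]*)$", "\\1", notation)   # drop the last '}'
        } else {
          paste0(notation, "{")
        }
      },
      whitespace = {
        at <- sample(nchar(notation) - 1L, 1L)
        paste0(substr(notation, 1L, at), " ",
               substr(notation, at + 1L, nchar(notation)))
      },
      bad_multiplier = paste0(notation, "{1}"),
      stereo_glyph = {
        target <- sample(which(forms == "smiles"), 1L)
        parts <- vapply(seq_along(comps), function(j) {
          txt <- if (j == target) paste0("@", comps[[j]]$text) else comps[[j]]$text
          m <- comps[[j]]$multiplier
          if (m > 1L) paste0(txt, "{", m, "}") else txt
        }, "")
        paste(parts, collapse = ".")
      },
      nonunary_composite = paste0(notation, ".C")
    )
    list(notation = mutated, error_class = paste0("csm_error_", kind))
  })
}
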