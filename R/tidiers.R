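# broom-style tidiers and a ggplot2 autoplot method, giving the parsed
# objects a tabular surface.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a molecular graph into an atom table
#'
#' @param x A `csm_graph`.
#' @param ... Unused.
#' @return A tibble with one row per atom: `atom` (1-based index), `symbol`,
#'   `aromatic`, `sqc`, `wildcard`, `isotope`, `hcount` (`NA` = implicit),
#'   `charge`, `n_annotations`, `annotations` (comma-separated markers).
#' @export
tidy.csm_graph <- function(x, ...) {
  tibble::tibble(
    atom = seq_along(x$atoms),
    symbol = vapply(x$atoms, `[[`, "", "symbol"),
    aromatic = vapply(x$atoms, `[[`, TRUE, "aromatic"),
    sqc = vapply(x$atoms, `[[`, TRUE, "is_sqc"),
    wildcard = vapply(x$atoms, `[[`, TRUE, "wildcard"),
    isotope = vapply(x$atoms, `[[`, 1L, "isotope"),
    hcount = vapply(x$atoms, `[[`, 1L, "hcount"),
    charge = vapply(x$atoms, `[[`, 1L, "charge"),
    n_annotations = vapply(x$atoms, function(a) length(a$annotations), 0L),
    annotations = vapply(x$atoms, function(a) {
      paste(vapply(a$annotations, `[[`, "", "marker"), collapse = ",")
    }, "")
  )
}

#' One-row summary of a molecular graph
#'
#' @param x A `csm_graph`.
#' @param ... Unused.
#' @return A one-row tibble: `n_atoms`, `n_bonds`, `n_ring_bonds`,
#'   `n_atom_annotations`, `n_component_annotations`, `net_charge`.
#' @export
glance.csm_graph <- function(x, ...) {
  tibble::tibble(
    n_atoms = length(x$atoms),
    n_bonds = length(x$bonds),
    n_ring_bonds = sum(vapply(x$bonds, function(b) isTRUE(b$ring), TRUE)),
    n_atom_annotations = sum(vapply(x$atoms, function(a) length(a$annotations), 0L)),
    n_component_annotations = length(x$caa),
    net_charge = sum(vapply(x$atoms, `[[`, 1L, "charge"))
  )
}

#' Tidy a stoichiometric composition into an element table
#'
#' @param x A `csm_sfn`.
#' @param ... Unused.
#' @return A tibble with `species` (element symbol, isotope-labelled species
#'   kept distinct) and `count`.
#' @export
tidy.csm_sfn <- function(x, ...) {
  tibble::tibble(species = names(x$flattened),
                 count = as.integer(x$flattened))
}

#' Per-component summary of a parsed notation
#'
#' @param x A `csm_notation`.
#' @param ... Unused.
#' @return A tibble with `component`, `form`, `multiplier`, `n_atoms`
#'   (`NA` for non-SMILES forms).
#' @export
tidy.csm_notation <- function(x, ...) {
  tibble::tibble(
    component = vapply(x$components, `[[`, "", "text"),
    form = vapply(x$components, `[[`, "", "form"),
    multiplier = vapply(x$components, `[[`, 1L, "multiplier"),
    n_atoms = vapply(x$components, function(comp) {
      if (comp$form == "smiles") length(comp$content$atoms) else NA_integer_
    }, 1L)
  )
}

#' Plot a molecular graph
#'
#' Draws the connectivity with a force-directed layout: atoms as labelled
#' points (annotated atoms highlighted), bonds as segments (ring-closure
#' bonds dashed). Purely topological — no 2D depiction conventions.
#'
#' @param object A `csm_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csm_graph <- function(object, ...) {
  n <- length(object$atoms)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(object$bonds)) {
    edges <- unlist(lapply(object$bonds, function(b) c(b$a, b$b)))
    ig <- igraph::add_edges(ig, edges)
  }
  xy <- igraph::layout_with_fr(ig)
  nodes <- tidy.csm_graph(object)
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  segs <- if (length(object$bonds)) {
    tibble::tibble(
      x = xy[vapply(object$bonds, `[[`, 1L, "a"), 1],
      y = xy[vapply(object$bonds, `[[`, 1L, "a"), 2],
      xend = xy[vapply(object$bonds, `[[`, 1L, "b"), 1],
      yend = xy[vapply(object$bonds, `[[`, 1L, "b"), 2],
      ring = vapply(object$bonds, function(b) isTRUE(b$ring), TRUE)
    )
  } else {
    tibble::tibble(x = numeric(0), y = numeric(0), xend = numeric(0),
                   yend = numeric(0), ring = logical(0))
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$ring),
      colour = "grey40", show.legend = FALSE
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = .data$n_annotations > 0),
      size = 6, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$symbol),
      colour = "white", size = 3
    ) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed")) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
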