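# Shared fixtures: the worked example notations exercised across the suite,
# and an igraph bridge for isomorphism checks (independent oracle).

example_notations <- c(
  cobalt_multiplier = "[Co+2].[O-]N(=O)=O{2}.O{6}",
  cobalt_exhaustive = "[Co+2].[O-]N(=O)=O.[O-]N(=O)=O.O.O.O.O.O.O",
  ionic_liquid      = "{bmim(1+)}.{NTf2(1-)}",
  customer_aliases  = "{$myCation}.{$myAnion}.{$mySolvate}{4}",
  carbide           = "{*Cr23C6}",
  bismuth_cation    = "{*Bi5(4+)}",
  azurite           = "{*Cu3(CO3)2(OH)2}",
  aurate            = "{*K(AuS(S2))}",
  polymer_composite = "{/N{-}=P{+n}(OCCOCCOC)(OCCOCCOC)/{*ZrO2}}",
  wildcard_pair     = "[*H2]=[*]",
  silica_surface    = "O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}",
  calixarene_unit   = "CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}",
  europium_complex  = "[Eu+3]{+Lc=CC(=O)COc1c{-}cc{-R}cc1C{+rn=4}}",
  grafted_alkyl     = "[*]{+Rn=4-16}{-|}"
)

# Element-coloured igraph view of a csm_graph, for vf2 isomorphism checks.
graph_as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$atoms), directed = FALSE)
  if (length(g$bonds)) {
    ig <- igraph::add_edges(ig, unlist(lapply(g$bonds, function(b) c(b$a, b$b))))
  }
  syms <- vapply(g$atoms, `[[`, "", "symbol")
  igraph::V(ig)$color <- as.integer(factor(syms, levels = sort(unique(syms))))
  ig
}

graphs_isomorphic <- function(g1, g2) {
  s1 <- vapply(g1$atoms, `[[`, "", "symbol")
  s2 <- vapply(g2$atoms, `[[`, "", "symbol")
  if (!identical(sort(s1), sort(s2))) return(FALSE)
  lev <- sort(unique(c(s1, s2)))
  ig1 <- graph_as_igraph(g1); igraph::V(ig1)$color <- as.integer(factor(s1, lev))
  ig2 <- graph_as_igraph(g2); igraph::V(ig2)$color <- as.integer(factor(s2, lev))
  igraph::isomorphic(ig1, ig2, method = "vf2")
}

entry_by_key <- function(ann, key) {
  for (e in ann$entries) if (identical(e$key, key)) return(e)
  NULL
}

write_alias_table <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
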