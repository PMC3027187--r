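Package: curlysmiles
Title: Parse, Validate and Transform Annotated Chemical Line Notations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parser, validator and transformation toolkit for CurlySMILES
    chemical line notations: a SMILES superset with curly-brace annotations
    for stereodescriptors, structural-unit boundaries, group environments
    (including surface attachment), molecular details, operational repeat
    units, and state/shape qualifiers, plus special component forms for
    stoichiometric formulas, aliases, composites and multipliers. Notations
    are parsed to molecular graphs and composition trees, validated against
    the grammar with classed conditions, expanded (multipliers, macrocycle
    and chain repeat units) and serialized back; a command-line interface
    and broom-style tidiers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
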