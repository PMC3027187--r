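# curlysmiles

Parsing, validation and transformation of **CurlySMILES** chemical line
notations in R.

Plain SMILES encodes a single, fully connected molecular graph — which is
not enough for much of materials chemistry and nanoscience, where the
species of interest are grafted to a silica surface, coordinated to a
rare-earth cation, repeated as a monomer unit in a macromolecule, or are
non-molecular solids best described by composition alone. CurlySMILES is a
SMILES superset for exactly these cases: curly-brace *annotations* anchored
to an atomic node (or to a whole component) carry stereodescriptors,
structural-unit boundaries (dangling bonds, so a methyl *group* `C{-}` is
distinct from the methyl *radical* `[CH3]`), group environments such as
surface attachment (`{-|}`), molecular details (`{!r...}`, e.g. a
delocalised ring charge), operational instructions (`{+rn=4}`: repeat the
unit four times into a macrocycle; `{+Lc=...}`: add a recursively encoded
ligand), and state/shape qualifiers. Special component forms cover
stoichiometric formulas `{*Cr23C6}`, aliases `{bmim(1+)}` / `{$custom}`,
interfacial composites `{/polymer/{*ZrO2}}` and trailing `{n}` multipliers.

The package is aimed at cheminformaticians and materials-data curators who
need to parse, check, compare, expand or strip such notations
programmatically — as a library, or from a shell via the bundled CLI.

## What it does

* **Lexing** — `csm_split_components()` splits a notation on dots at brace
  depth zero, classifies each component (SMILES / alias / formula /
  composite) and detaches `{n}` multipliers (`n ≥ 2` by definition).
* **Graphs** — `csm_parse_smiles()` builds the molecular graph (atoms,
  bonds, annotations); the dialect's rules are enforced: `~`/`$` bonds and
  the `*` wildcard require square-bracket atomic codes, and the stereo
  glyphs `@ / \` are rejected in favour of `{R}`, `{Z}`, ... annotations.
* **Annotations** — `csm_parse_annotation()` classifies markers into the
  seven annotation classes and parses `key=value` dictionaries whose values
  may recursively be full notations; `csm_resolve_pointer()` follows
  relative node pointers such as `{-|i=-2}`.
* **Formulas** — `csm_parse_sfn()` flattens nested stoichiometric groups
  with isotope labels and terminal charges; `csm_compare_sfn()` compares
  compositions order-insensitively; `csm_formula()` derives a composition
  from a graph (implicit hydrogens by standard valence).
* **Transforms** — `csm_expand_multipliers()` (exhaustive notation),
  `csm_expand_ring()` / `csm_expand_chain()` (macrocycle and chain repeat
  units), `csm_strip_annotations()` (with a strict policy refusing to
  change chemical identity).
* **Tooling** — classed error conditions with character offsets, broom-style
  `tidy()`/`glance()` methods, `autoplot()`, a deterministic fixture
  generator (`csm_generate()`, `csm_mutate_invalid()`), and a CLI.

## Worked example

Cobalt(II) nitrate hexahydrate, Co(NO₃)₂·6H₂O, in multiplier notation:

```r
library(curlysmiles)
x <- csm_parse("[Co+2].[O-]N(=O)=O{2}.O{6}")
tidy(x)
#> # A tibble: 3 × 4
#>   component   form   multiplier n_atoms
#>   <chr>       <chr>       <int>   <int>
#> 1 [Co+2]      smiles          1       1
#> 2 [O-]N(=O)=O smiles          2       4
#> 3 O           smiles          6       1

csm_serialize(csm_expand_multipliers(x))
#> [1] "[Co+2].[O-]N(=O)=O.[O-]N(=O)=O.O.O.O.O.O.O"
```

The three components are the cobalt cation, the nitrate anion (counted
twice) and water (counted six times); expansion rewrites the multipliers
into the exhaustive, one-copy-per-count form. Compositions flatten through
arbitrary nesting — azurite:

```r
csm_parse("{*Cu3(CO3)2(OH)2}")$components[[1]]$content
#> <stoichiometric composition: Cu3(CO3)2(OH)2>
#>   Cu     3
#>   C      2
#>   O      8
#>   H      2
```

and an imidazolium species immobilised on a silica surface parses to a
12-atom graph whose four annotations encode the two surface attachments
(one by formula, one by relative pointer `i=-2`), the alkyl substituent
and the delocalised ring charge:

```r
g <- csm_parse_smiles("O{-|sfn=SiO2}[Si](O{-|i=-2})(O)CCCn1ccn{-R}c1{!re=+}")
glance(g)
#> # A tibble: 1 × 6
#>   n_atoms n_bonds n_ring_bonds n_atom_annotations n_component_annotations net_charge
#> 1      12      12            1                  4                       0          0
```

From a shell:

```sh
Rscript inst/cli/curlysmiles parse "{*Cr23C6}"
Rscript inst/cli/curlysmiles expand "[Co+2].[O-]N(=O)=O{2}.O{6}"
Rscript inst/cli/curlysmiles match-sfn "{*C6Cr23}" "{*Cr23C6}"
```

(After installation the launcher lives at
`system.file("cli", "curlysmiles", package = "curlysmiles")`.)

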