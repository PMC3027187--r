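---
title: "The annotated notation grammar: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The annotated notation grammar: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curlysmiles)
```

## The notation model

A notation is a string of dot-separated *component notations*. A component
is either a SMILES-form notation (plain or annotated) or a special form
that begins with `{`: a stoichiometric formula `{*...}`, an alias
`{name}` / `{$customer}`, or a composite `{/c1/c2/.../cn}`. A trailing
`{n}` block with `n ≥ 2` is a *multiplier*, not an annotation: it repeats
the whole component, and expansion to one copy per count gives the
exhaustive notation.

Because annotation dictionaries can embed entire recursive notations
(a coordinated ligand is written `{+Lc=<notation>}`), the lexer tracks
nesting of `{}`, `[]` and `()` jointly and splits on `.` only when all
three depths are zero. The same rule governs `;` splitting inside
dictionaries and `/` splitting inside composites.

## Annotations and anchoring

An annotation is the text between one `{`/`}` pair. Seven marker classes
partition the space, resolved by longest match:

| class  | marker shape                          | anchored to | example |
|--------|---------------------------------------|-------------|---------|
| stereo | one of `D E L R S Z`                  | atom        | `{R}` |
| unit   | one bond symbol `- = # : & ~`         | atom        | `{-}` (dangling bond) |
| geam   | bond symbol or `.` + `Y R X \|`       | atom        | `{-\|sfn=SiO2}` |
| mdam   | `!` + `a p m r H I`                   | atom        | `{!re=+}` |
| opam   | `+` + `R X Y L n r`                   | atom        | `{+rn=4}` |
| ssam   | two lower-case letters                | component   | `{aq}` |
| miam   | other two-character marker            | component   | `{Dp}` |

A lone upper-case stereodescriptor or a lone bond symbol is a complete
annotation; everything else must present a two-character marker followed by
an optional dictionary of `;`-separated `key=value` entries. Keys start
with a letter or `$` (customer-defined; never validated against the
registry). Values are typed opportunistically — integers, `lo-hi` ranges,
charge tokens, and full notations under key `c` — and are otherwise kept as
verbatim text, so dictionary re-serialisation is byte-exact.

Atom-anchored annotations must directly follow their atomic node code; only
ring-closure digits (and earlier annotations on the same atom) may
intervene. Component-anchored classes must terminate the component. The
parser enforces both directions: an `{aq}` in the middle of a chain and an
`{R}` after a branch close are positional errors.

Relative pointers (`{-\|i=-2}`) move along atom appearance order from their
anchor; resolution additionally requires the referenced node to carry a
group-environment annotation with the same marker (the surface description
being pointed at), so a pointer can never silently bind to an unrelated
atom.

## Graph rules of the dialect

The SMILES subset follows common practice (organic-subset bare atoms,
square-bracket codes with isotope/H-count/charge, branches, single-digit
and `%nn` ring labels), with three dialect-specific rules enforced as hard
errors:

* the wildcard atom must be written `[*]` — never bare;
* `~` (unspecified) and `$` (quadruple) bonds require square-bracket
  codes on *both* endpoints;
* the stereo glyphs `@`, `/`, `\` are rejected with a pointer to the
  stereodescriptor annotations.

Boundary descriptors `:`, `&`, `~` in structural-unit annotations require a
square-bracket anchor; `-`, `=`, `#` are legal on bare organic-subset
atoms. No aromaticity perception, kekulisation or valence checking is
performed: lower-case symbols set a purely syntactic aromatic flag, and the
default bond between two aromatic atoms is aromatic, otherwise single.

## Deliberate design choices

Several points are genuinely open in the notation definition; the package
resolves them as follows, once:

* **Multiplier `{1}` and `{0}` are errors**, not no-ops — a multiplier is
  defined as an integer greater than one, and silently accepting `{1}`
  would make round-tripping ambiguous.
* **A composite takes no multiplier** and must be the entire notation
  (unary rule); both violations are rejected at lexing time.
* **`&` as a graph bond** is accepted but stored as an *ambiguous* order
  with a warning: the symbol is defined for boundary descriptors, and its
  chemical meaning in bond position is left open, so it is round-tripped
  opaquely rather than guessed at.
* **The typeset marker `. |`** (ionic surface interaction) is normalised to
  the contiguous `.|`; all other markers are contiguous.
* **Registries are seeds.** The full registries of predefined aliases,
  dictionary keys and state/shape markers are external, extensible
  resources. The package ships small editable seed files
  (`inst/extdata/`); unknown dictionary keys and ssam/miam markers warn,
  while alias lookups that fall through every table are errors (an alias
  has no meaning at all without its replacement). The ssam/miam seed
  entries are synthetic placeholders.
* **Alias keys include the charge suffix** (`bmim(1+)`, not `bmim`), and
  `$` stays part of the customer key, so predefined and customer namespaces
  cannot collide.
* **Ring expansion copies per-unit annotations** (the calixarene's `{-R}`
  appears once per repeat unit); the `+r` atom of each copy bonds to the
  boundary atom of the *next* copy and the last closes onto the first, with
  the join-bond order taken from the boundary descriptor. Chain expansion
  leaves the two terminal open bonds dangling and marks them as
  structural-unit boundaries.
* **Implicit hydrogens** on bare organic-subset atoms are materialised only
  on demand (formula derivation) from the standard valence table (B 3; C 4;
  N 3,5; O 2; P 3,5; S 2,4,6; halogens 1), counting aromatic bonds as 1.5.
  Square-bracket codes carry their H count explicitly (zero when absent).
* **Serialisation keeps source text.** Parsed components remember their
  source, so parse → serialise is byte-identical; only programmatically
  built graphs (expansions) go through the depth-first writer, for which
  parse → serialise → parse is a fixed point.

## What the fixture generator emulates — and what it does not

`csm_generate()` produces grammar-covering notations with ground truth
recorded by generator bookkeeping (atom/bond counts, flattened
compositions, planted annotation anchors and pointer targets, component
multiplicities), deterministically per seed. Its limits are deliberate —
at most 20 atoms per component, 5 components, group nesting depth 3 — so
that brute-force oracles stay trivial. It makes no attempt at chemical
sensibility: valences can be absurd, aromaticity is not closed into rings,
and compositions are random. Passing the property suites therefore
demonstrates grammatical correctness, round-trip stability and error
detection, not chemical validity of real-world archives.
`csm_mutate_invalid()` plants exactly one corruption with a recorded error
class, which the parser must reproduce exactly.

The test suite runs the property checks at 500 fuzzed formulas and 500
fuzzed notations, repeat-unit expansions at 2–6 copies, and the corruption
corpus at roughly 130 mutants; these sizes were chosen so the whole suite
stays interactive while each property still covers every generator branch
many times over.

## Known limitations

* Chemical interpretation beyond syntax is out of scope: stereodescriptors
  are stored, not verified against CIP rules; aromatic flags are not
  perceived or kekulised; valence violations are not errors.
* Canonicalisation is not attempted — equality of two notations is
  decidable at the composition level (`csm_compare_sfn()`) or by graph
  isomorphism on parsed graphs, not at the string level.
* The `!a/!p/!m/!H/!I` molecular-detail markers and miscellaneous-interest
  annotations are stored and round-tripped opaquely; their detailed
  vocabularies live in external registries.
* Substitution-type operational annotations (`+R`, `+X`, `+Y`) and generic
  environments (`-Y`) are preserved as pattern nodes; full substructure
  matching over them is not implemented.
* Symbolic ranges (`n=4-16`) are kept symbolic; the package does not
  enumerate the family of explicit molecules they denote.
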