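# Element tables. The 118 IUPAC symbols are bundled so that stoichiometric
# formulas and square-bracket atomic codes can be tokenised greedily
# (two-letter symbols before one-letter: "Co" is cobalt, never C + O).

CSM_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Elements writable without brackets in SMILES (organic subset); hydrogens
# implied by standard valence.
CSM_ORGANIC_1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
CSM_ORGANIC_2 <- c("Cl", "Br")
CSM_AROMATIC_BARE <- c("b", "c", "n", "o", "p", "s")
CSM_AROMATIC_SQC  <- c("b", "c", "n", "o", "p", "s", "se", "as")

# Bond symbols of the dialect; '&' is accepted in bond position but its
# chemical meaning is left open (stored as an ambiguous bond).
CSM_BOND_SYMS <- c("-", "=", "#", ":", "$", "~", "&")

# Numeric bond orders used when materialising implicit hydrogens.
csm_bond_order_num <- function(sym) {
  switch(sym,
    "-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
    "~" = 1, "&" = 1
  )
}

# Standard valences for implicit-hydrogen materialisation on organic-subset
# bare atoms (smallest valence >= bonds already drawn is used).
CSM_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

csm_is_element <- function(sym) sym %in% CSM_ELEMENTS
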