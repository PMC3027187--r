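# Seed registry of predefined dictionary keys (key<TAB>description).
# Unknown non-$ keys warn rather than error: the full key registry is an
# external, extensible resource.
sfn	stoichiometric formula of an attached or surrounding material
i	relative pointer to another atomic node (signed offset in appearance order)
n	integer count or integer range (e.g. repeat units, carbon atoms)
c	recursively parsed notation (e.g. a ligand)
e	delocalized charge token (e.g. + for a positive ring charge)
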