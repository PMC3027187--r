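# Seed table of predefined aliases (alias<TAB>replacement notation).
# The full predefined registry is an external, extensible resource; this
# file is an editable placeholder covering common ionic-liquid ions.
bmim(1+)	CCCCn1cc[n+](C)c1
emim(1+)	CCn1cc[n+](C)c1
NTf2(1-)	[N-](S(=O)(=O)C(F)(F)F)S(=O)(=O)C(F)(F)F
BF4(1-)	[B-](F)(F)(F)F
PF6(1-)	[P-](F)(F)(F)(F)(F)F
OTf(1-)	[O-]S(=O)(=O)C(F)(F)F
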