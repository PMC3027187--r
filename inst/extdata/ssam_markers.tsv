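# Seed registry of state-and-shape annotation markers (marker<TAB>description).
# Synthetic placeholder entries: the authoritative registry is an external,
# extensible resource, so unknown markers warn rather than error.
aq	aqueous solution
cr	crystalline phase
am	amorphous phase
np	nanoparticle
nt	nanotube
tf	thin film
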