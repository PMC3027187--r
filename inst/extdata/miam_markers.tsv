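# Seed registry of miscellaneous-interest annotation markers.
# Synthetic placeholder entries; unknown markers warn rather than error.
Dp	dopant of the encoded host material
Rf	reference tag attached by an archive
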