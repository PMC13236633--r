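CTL	cytotoxic T lymphocyte markers	CD8A	CD8B	GZMA	GZMB	GZMK	PRF1	IFNG	NKG7	KLRK1	CTSW
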