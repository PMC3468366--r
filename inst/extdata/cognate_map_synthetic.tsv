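amino_acid	cog_ids
K	COG0001
E	COG0002
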