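# example batch query: NAME : FEATURES : COG_LIST
ArgGroup : R : COG0001, COG0002
KGroup : K : COG0001
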