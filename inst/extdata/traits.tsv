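organism_id	oxygen_class	ogt
eco	aerobe	
mja	anaerobe	85
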