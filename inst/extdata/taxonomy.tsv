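organism_id	superkingdom	phylum	class	order	family	genus	species
eco	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacterales	Enterobacteriaceae	Escherichia	Escherichia coli
mja	Archaea	Euryarchaeota	Methanococci	Methanococcales	Methanocaldococcaceae		Methanocaldococcus jannaschii
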