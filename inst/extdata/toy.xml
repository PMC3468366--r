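<?xml version="1.0" encoding="UTF-8"?>
<dataset source="cog">
  <organism id="eco" name="Escherichia coli K-12"/>
  <organism id="mja" name="Methanocaldococcus jannaschii"/>
  <cog id="COG0001" desc="Ribosomal protein S1">
    <seq org="eco" protein_gi="p1" gene_gi="g1">
      <aa>MKKR</aa>
      <nt>ATGAAAAAACGATAA</nt>
    </seq>
    <seq org="mja" protein_gi="p2" gene_gi="g2">
      <aa>mkr</aa>
      <nt>augaaacga</nt>
    </seq>
  </cog>
  <cog id="COG0002" desc="Glutamate synthase">
    <seq org="eco" protein_gi="p3" gene_gi="g3">
      <aa>MQHE</aa>
      <nt>ATGCAACATGAA</nt>
    </seq>
    <seq org="mja" protein_gi="p4" gene_gi="g4">
      <aa>MX*</aa>
    </seq>
  </cog>
</dataset>
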