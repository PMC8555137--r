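<?xml version="1.0"?>
<pathway name="path:syn001" org="syn" number="001" title="synthetic toy pathway">
  <entry id="1" name="GENE_A" type="gene"/>
  <entry id="2" name="GENE_B" type="gene"/>
  <entry id="3" name="GENE_C" type="gene"/>
  <entry id="4" name="cpd:C001" type="compound"/>
  <entry id="5" name="GENE_D" type="gene"/>
  <entry id="6" name="GENE_E" type="gene"/>
  <entry id="7" name="undefined" type="group">
    <component id="5"/>
    <component id="6"/>
  </entry>
  <entry id="8" name="GENE_F" type="gene"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="phosphorylation" value="+p"/>
  </relation>
  <relation entry1="3" entry2="4" type="PCrel"/>
  <relation entry1="4" entry2="8" type="PCrel"/>
  <relation entry1="2" entry2="7" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
</pathway>
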