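<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:synpw1" title="Urea cycle (toy analog)">
  <entry id="1" name="cpd:CX001" type="compound"><graphics name="carbamoyl-P*"/></entry>
  <entry id="2" name="cpd:CX002" type="compound"><graphics name="ornithine*"/></entry>
  <entry id="3" name="cpd:CX003" type="compound"><graphics name="citrulline*"/></entry>
  <entry id="4" name="cpd:CX004" type="compound"><graphics name="argininosuccinate*"/></entry>
  <entry id="5" name="cpd:CX005" type="compound"><graphics name="arginine*"/></entry>
  <entry id="6" name="cpd:CX006" type="compound"><graphics name="urea*"/></entry>
  <entry id="7" name="gsy:OTCx" type="gene" reaction="rn:RX01"><graphics name="OTCx"/></entry>
  <entry id="8" name="gsy:ASS1x" type="gene" reaction="rn:RX02"><graphics name="ASS1x"/></entry>
  <entry id="9" name="gsy:ASLx" type="gene" reaction="rn:RX03"><graphics name="ASLx"/></entry>
  <entry id="10" name="gsy:ARG1x" type="gene" reaction="rn:RX04"><graphics name="ARG1x"/></entry>
  <reaction id="11" name="rn:RX01" type="irreversible">
    <substrate id="1"/><substrate id="2"/><product id="3"/>
  </reaction>
  <reaction id="12" name="rn:RX02" type="irreversible">
    <substrate id="3"/><product id="4"/>
  </reaction>
  <reaction id="13" name="rn:RX03" type="irreversible">
    <substrate id="4"/><product id="5"/>
  </reaction>
  <reaction id="14" name="rn:RX04" type="irreversible">
    <substrate id="5"/><product id="2"/><product id="6"/>
  </reaction>
</pathway>
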