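<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:synpw2" title="De novo pyrimidine biosynthesis (toy analog)">
  <entry id="1" name="cpd:CX000" type="compound"><graphics name="glutamine*"/></entry>
  <entry id="2" name="cpd:CX001" type="compound"><graphics name="carbamoyl-P*"/></entry>
  <entry id="3" name="cpd:CX010" type="compound"><graphics name="aspartate*"/></entry>
  <entry id="4" name="cpd:CX011" type="compound"><graphics name="carbamoyl-aspartate*"/></entry>
  <entry id="5" name="cpd:CX012" type="compound"><graphics name="dihydroorotate*"/></entry>
  <entry id="6" name="cpd:CX013" type="compound"><graphics name="orotate*"/></entry>
  <entry id="7" name="gsy:CPS1x" type="gene" reaction="rn:RX10"><graphics name="CPS1x"/></entry>
  <entry id="8" name="gsy:CADx" type="gene" reaction="rn:RX11 rn:RX12"><graphics name="CADx"/></entry>
  <entry id="9" name="gsy:DHODHx" type="gene" reaction="rn:RX13"><graphics name="DHODHx"/></entry>
  <entry id="10" name="gsy:SIGx" type="gene"><graphics name="SIGx"/></entry>
  <reaction id="11" name="rn:RX10" type="irreversible">
    <substrate id="1"/><product id="2"/>
  </reaction>
  <reaction id="12" name="rn:RX11" type="irreversible">
    <substrate id="2"/><substrate id="3"/><product id="4"/>
  </reaction>
  <reaction id="13" name="rn:RX12" type="irreversible">
    <substrate id="4"/><product id="5"/>
  </reaction>
  <reaction id="14" name="rn:RX13" type="irreversible">
    <substrate id="5"/><product id="6"/>
  </reaction>
  <relation entry1="10" entry2="8" type="PPrel">
    <subtype name="activation" value=""/>
  </relation>
</pathway>
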