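cpd:CX000	substrate_to_gene	gsy:CPS1x
cpd:CX001	substrate_to_gene	gsy:CADx
cpd:CX001	substrate_to_gene	gsy:OTCx
cpd:CX002	substrate_to_gene	gsy:OTCx
cpd:CX010	substrate_to_gene	gsy:CADx
cpd:CX011	substrate_to_gene	gsy:CADx
gsy:CADx	gene_to_product	cpd:CX011
gsy:CADx	gene_to_product	cpd:CX012
gsy:CPS1x	gene_to_product	cpd:CX001
gsy:OTCx	gene_to_product	cpd:CX003
gsy:SIGx	gene_to_gene	gsy:CADx
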