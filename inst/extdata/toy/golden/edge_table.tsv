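source	target	edge_type	provenance
cpd:CX000	gsy:CPS1x	substrate_to_gene	synpw2:11
cpd:CX001	gsy:CADx	substrate_to_gene	synpw2:12
cpd:CX001	gsy:OTCx	substrate_to_gene	synpw1:11
cpd:CX002	gsy:OTCx	substrate_to_gene	synpw1:11
cpd:CX010	gsy:CADx	substrate_to_gene	synpw2:12
cpd:CX011	gsy:CADx	substrate_to_gene	synpw2:13
gsy:CADx	cpd:CX011	gene_to_product	synpw2:12
gsy:CADx	cpd:CX012	gene_to_product	synpw2:13
gsy:CPS1x	cpd:CX001	gene_to_product	synpw2:11
gsy:OTCx	cpd:CX003	gene_to_product	synpw1:11
gsy:SIGx	gsy:CADx	gene_to_gene	synpw2:rel1
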