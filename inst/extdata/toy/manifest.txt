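seeds=gsy:CADx,gsy:CPS1x
shared_compound=cpd:CX001
merged.n_metabolites=11
merged.n_metabolic_genes=7
merged.n_signaling_genes=1
merged.n_nodes=19
merged.n_edges=20
after_distance.n_metabolites=8
after_distance.n_metabolic_genes=4
after_distance.n_signaling_genes=1
after_distance.n_nodes=13
after_distance.n_edges=13
after_expression.n_metabolites=8
after_expression.n_metabolic_genes=3
after_expression.n_signaling_genes=1
after_expression.n_nodes=12
after_expression.n_edges=11
final.n_metabolites=7
final.n_metabolic_genes=3
final.n_signaling_genes=1
final.n_nodes=11
final.n_edges=11
distance.gsy:CPS1x=0
distance.gsy:CADx=0
distance.cpd:CX000=1
distance.cpd:CX001=1
distance.cpd:CX010=1
distance.cpd:CX011=1
distance.cpd:CX012=1
distance.gsy:SIGx=1
distance.gsy:OTCx=2
distance.gsy:DHODHx=2
distance.cpd:CX002=3
distance.cpd:CX003=3
distance.cpd:CX013=3
distance.gsy:ASS1x=4
distance.gsy:ARG1x=4
distance.cpd:CX004=5
distance.cpd:CX005=5
distance.cpd:CX006=5
distance.gsy:ASLx=6
final_nodes=cpd:CX000,cpd:CX001,cpd:CX002,cpd:CX003,cpd:CX010,cpd:CX011,cpd:CX012,gsy:CADx,gsy:CPS1x,gsy:OTCx,gsy:SIGx
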