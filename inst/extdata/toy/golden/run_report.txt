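build.n_metabolites=11
build.n_metabolic_genes=7
build.n_signaling_genes=1
build.n_nodes=19
build.n_edges=20
distance_filter.n_metabolites=8
distance_filter.n_metabolic_genes=4
distance_filter.n_signaling_genes=1
distance_filter.n_nodes=13
distance_filter.n_edges=13
annotate.n_metabolites=8
annotate.n_metabolic_genes=4
annotate.n_signaling_genes=1
annotate.n_nodes=13
annotate.n_edges=13
expression_filter.n_metabolites=8
expression_filter.n_metabolic_genes=3
expression_filter.n_signaling_genes=1
expression_filter.n_nodes=12
expression_filter.n_edges=11
prune.n_metabolites=7
prune.n_metabolic_genes=3
prune.n_signaling_genes=1
prune.n_nodes=11
prune.n_edges=11
join.expression.n_records=8
join.expression.n_matched=5
join.expression.n_unmatched=3
join.expression.unmatched_ids=gsy:ARG1x,gsy:ASLx,gsy:ASS1x
join.prognosis.n_records=5
join.prognosis.n_matched=4
join.prognosis.n_unmatched=1
join.prognosis.unmatched_ids=gsy:ASS1x
join.biofluid.n_records=4
join.biofluid.n_matched=3
join.biofluid.n_unmatched=1
join.biofluid.unmatched_ids=cpd:CX006
removed.distance_filter=cpd:CX004,cpd:CX005,cpd:CX006,gsy:ARG1x,gsy:ASLx,gsy:ASS1x
removed.expression_filter=gsy:DHODHx
removed.prune=cpd:CX013
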