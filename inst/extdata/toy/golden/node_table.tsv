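node_id	label	kind	is_seed	distance	expression_value	prognosis	prognosis_p	urine_normal	urine_abnormal
gsy:CADx	CADx	metabolic_gene	true	0	35.1	unfavorable	1.72e-11		
gsy:CPS1x	CPS1x	metabolic_gene	true	0	120.5	favorable	6.93e-05		
gsy:OTCx	OTCx	metabolic_gene	false	2	80.2	none	0.005		
cpd:CX000	glutamine*	metabolite	false	1				true	true
cpd:CX001	carbamoyl-P*	metabolite	false	1					
cpd:CX002	ornithine*	metabolite	false	3				true	false
cpd:CX003	citrulline*	metabolite	false	3					
cpd:CX010	aspartate*	metabolite	false	1					
cpd:CX011	carbamoyl-aspartate*	metabolite	false	1					
cpd:CX012	dihydroorotate*	metabolite	false	1					
gsy:SIGx	SIGx	signaling_gene	false	1	12.7	none	0.2		
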