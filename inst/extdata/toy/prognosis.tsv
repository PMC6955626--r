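gene_id	direction	logrank_p
gsy:CPS1x	favorable	6.93e-05
gsy:CADx	unfavorable	1.72e-11
gsy:OTCx	favorable	0.005
gsy:ASS1x	unfavorable	0.001
gsy:SIGx	unfavorable	0.2
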