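gene_id	tissue	value
gsy:CPS1x	hepatocytes	120.5
gsy:CADx	hepatocytes	35.1
gsy:OTCx	hepatocytes	80.2
gsy:ASS1x	hepatocytes	60
gsy:ASLx	hepatocytes	0
gsy:ARG1x	hepatocytes	45.3
gsy:DHODHx	hepatocytes	0
gsy:SIGx	hepatocytes	12.7
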