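metabolite_id	in_normal_urine	in_abnormal_urine
cpd:CX000	true	true
cpd:CX002	true	false
cpd:CX006	true	true
cpd:CX013	false	true
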