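gene	evalue_cutoff
menB	1e-12
menC	1e-12
menF	1e-10
mqnA	1e-10
mqnC	1e-10
mqnD	1e-10
ubiA	1e-12
ubiC	1e-08
ubiG	1e-10
nuoA	1e-10
nuoE	1e-10
nuoJ	1e-10
ndh	1e-12
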