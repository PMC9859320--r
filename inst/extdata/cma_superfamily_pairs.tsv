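family_a	family_b
CmaSat01-144	CmaSat04-141
CmaSat02-543	CmaSat08-285
CmaSat05-247	CmaSat32-237
CmaSat11-234	CmaSat24-327
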