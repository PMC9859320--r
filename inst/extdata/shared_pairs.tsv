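family_a	family_b	similarity	classification
PmeSat02-143	CmaSat04-141	78.3	SF
PmeSat02-143	CmaSat01-144	67.5	SF
PmeSat07-42	CmaSat09-42	97.6	SV
PmeSat05-247	CmaSat05-247	72.5	SF
PmeSat05-247	CmaSat32-237	59.7	SF
PmeSat08-177	CmaSat03-177	87	V
PmeSat10-21	CmaSat15-21	100	SV
PmeSat11-1242	CmaSat36-1250	87	V
PmeSat12-72	CmaSat20-72	97.2	SV
PmeSat14-956	CmaSat16-955	91.4	V
PmeSat15-170	CmaSat14-157	73.5	SF
PmeSat17-65	CmaSat22-68	95.5	SV
PmeSat18-67	CmaSat33-66	98.5	SV
PmeSat19-30	CmaSat18-30	100	SV
PmeSat21-54	CmaSat31-54	98.1	SV
PmeSat22-28	CmaSat21-28	96.4	SV
PmeSat23-38	CmaSat19-38	81.5	V
PmeSat25-6	CmaSat25-6	100	SV
PmeSat27-102	CmaSat34-101	97	SV
PmeSat28-398	CmaSat27-398	91.2	V
PmeSat29-30	CmaSat38-30	90	V
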