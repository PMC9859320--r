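Cma	Pme	Mma	Mel	Cgo	Pli	Tau
CmaSat09-42	PmeSat07-42	MmaSat07-42	MelSat08-42	CgoSat10-42	PliSat12-42	TauSat06-42
CmaSat15-21	PmeSat10-21	-	-	-	PliSat17-21	-
CmaSat18-30	PmeSat19-30	-	MelSat25-30	-	PliSat19-30	-
CmaSat20-72	PmeSat12-72	-	-	-	PliSat15-75	TauSat19-76
CmaSat21-28	PmeSat22-28	MmaSat41-29	MelSat48-29	CgoSat26-29	-	TauSat16-29
CmaSat22-68	PmeSat17-65	MmaSat84-65	MelSat39-65	-	PliSat36-68	TauSat12-66
CmaSat31-54	PmeSat21-54	MmaSat38-54	-	-	-	-
CmaSat33-66	PmeSat18-67	MmaSat27-67	MelSat12-67	-	PliSat16-67	-
CmaSat35-30	-	MmaSat57-30	MelSat58-31	-	PliSat30-31	-
CmaSat38-30	PmeSat29-30	-	MelSat54-30	-	PliSat32-30	-
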