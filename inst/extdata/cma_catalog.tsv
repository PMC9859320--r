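name	rul	at_content	abundance	divergence
CmaSat01-144	144	56.2	0.01389	6.62
CmaSat02-543	543	58.0	0.00534	13.07
CmaSat03-177	177	64.9	0.00515	4.27
CmaSat04-141	141	57.4	0.00464	5.22
CmaSat05-247	247	63.1	0.00447	26.04
CmaSat06-3168	3168	57.0	0.00399	14.69
CmaSat07-525	525	57.1	0.00318	1.99
CmaSat08-285	177	58.5	0.00280	8.90
CmaSat09-42	42	54.7	0.00166	12.92
CmaSat10-43	43	48.8	0.00158	19.89
CmaSat11-234	1242	57.2	0.00130	5.46
CmaSat12-1846	1846	66.3	0.00103	5.91
CmaSat13-2220	2220	60.0	0.00100	12.00
CmaSat14-170	170	56.4	0.00095	0.03
CmaSat15-21	21	76.1	0.00089	17.19
CmaSat16-955	955	63.2	0.00076	0.73
CmaSat17-1946	1946	53.5	0.00060	7.25
CmaSat18-30	30	56.6	0.00058	9.28
CmaSat19-38	38	65.7	0.00055	6.71
CmaSat20-72	72	65.2	0.00054	3.10
CmaSat21-28	28	53.5	0.00051	10.39
CmaSat22-68	68	63.2	0.00049	5.11
CmaSat23-898	898	59.9	0.00046	12.74
CmaSat24-327	327	52.5	0.00046	3.34
CmaSat25-6	6	50.0	0.00046	20.53
CmaSat26-50	50	64.0	0.00043	4.40
CmaSat27-394	394	55.5	0.00041	4.28
CmaSat28-183	183	53.5	0.00035	4.23
CmaSat29-34	34	70.5	0.00034	17.93
CmaSat30-919	919	67.2	0.00034	14.39
CmaSat31-54	54	53.7	0.00034	8.78
CmaSat32-237	237	59.4	0.00032	16.73
CmaSat33-66	66	65.1	0.00032	6.47
CmaSat34-101	101	60.3	0.00031	6.93
CmaSat35-30	30	53.3	0.00029	11.94
CmaSat36-1250	1250	59.9	0.00024	2.49
CmaSat37-51	51	62.7	0.00021	2.66
CmaSat38-30	30	63.3	0.00019	11.07
CmaSat39-192	192	61.9	0.00015	7.47
CmaSat40-932	932	51.0	0.00014	2.00
CmaSat41-263	263	57.7	0.00014	9.78
CmaSat42-83	83	60.2	0.00013	10.92
CmaSat43-62	62	61.2	0.00012	7.20
CmaSat44-324	324	68.2	0.00011	9.01
CmaSat45-289	289	62.2	0.00010	4.82
CmaSat46-30	30	43.3	0.00009	6.48
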