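name	rul	at_content	abundance	divergence
PmeSat01-508	508	58.6	0.00938	8.10
PmeSat02-143	143	55.9	0.00837	10.74
PmeSat03-1068	1068	58.8	0.00752	11.85
PmeSat04-118	118	62.7	0.00322	10.75
PmeSat05-247	247	61.9	0.00192	18.62
PmeSat06-1853	1853	56.1	0.00173	8.38
PmeSat07-42	42	52.3	0.00112	15.06
PmeSat08-177	177	65.5	0.00092	14.96
PmeSat09-696	696	66.6	0.00076	7.88
PmeSat10-21	21	76.1	0.00069	16.97
PmeSat11-1242	1242	58.5	0.00064	1.82
PmeSat12-72	72	68.0	0.00053	6.72
PmeSat13-92	92	73.9	0.00051	4.75
PmeSat14-956	956	63.2	0.00051	1.48
PmeSat15-157	157	50.3	0.00051	5.05
PmeSat16-42	42	45.2	0.00044	12.12
PmeSat17-65	65	63.0	0.00038	6.26
PmeSat18-67	67	65.6	0.00036	9.11
PmeSat19-30	30	56.6	0.00035	10.15
PmeSat20-142	142	57.0	0.00033	13.53
PmeSat21-54	54	51.8	0.00031	10.04
PmeSat22-28	28	50.0	0.00030	10.87
PmeSat23-38	38	63.1	0.00026	8.25
PmeSat24-83	83	54.2	0.00023	9.93
PmeSat25-6	6	50.0	0.00021	23.98
PmeSat26-81	81	64.1	0.00021	7.68
PmeSat27-102	102	59.8	0.00019	11.35
PmeSat28-398	398	57.2	0.00017	6.54
PmeSat29-30	30	60.0	0.00016	13.14
PmeSat30-33	33	63.6	0.00006	5.67
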