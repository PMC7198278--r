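source_class	fdr_flag	trait	study	chrom	pos_mb_start	pos_mb_end	candidate_gene
this_study	0	Plant height (cm)	this_study	Pv01	6.13	6.13	Phvul.001G054800
this_study	1	Growth habit	this_study	Pv01	6.28	6.28	Phvul.001G055600
this_study	0	Biomass (kg)	this_study	Pv01	6.49	6.49	Phvul.001G057100
published	0	Lodging score	pub01	Pv01	13.76	13.76	Phvul.001G087900
published	0	Growth habit	pub01	Pv01	13.76	13.76	Phvul.001G087900
published	0	Days to flowering	pub02	Pv01	13.76	13.76	Phvul.001G087900
this_study	1	Days to flowering	this_study	Pv01	13.45	15.36	Phvul.001G087900
published	0	Root rot damage	pub03	Pv01	23.92	23.92	NA
published	0	Days to flower	pub04	Pv01	27.68	27.68	NA
published	0	Root rot damage	pub03	Pv01	33.03	33.03	NA
this_study	0	Halo blight damage score	this_study	Pv01	36.72	36.72	Phvul.001G132516
published	0	Root rot damage	pub03	Pv01	37.20	37.20	NA
this_study	0	Plant height (cm)	this_study	Pv01	38.74	38.74	Phvul.001G143800
published	0	Root rot damage	pub03	Pv01	40.20	40.20	NA
this_study	1	Growth habit	this_study	Pv01	42.17	42.17	Phvul.001G167200
this_study	1	Seed yield	this_study	Pv01	42.23	42.23	Phvul.001G167200
published	0	Growth habit	pub02	Pv01	42.23	42.23	Phvul.001G167200
this_study	0	Biomass (kg)	this_study	Pv01	42.27	42.27	Phvul.001G167200
published	0	Growth habit	pub08	Pv01	44.80	44.80	Phvul.001G189200
published	0	Growth habit	pub02	Pv01	44.80	44.80	Phvul.001G192200
published	0	Days to flowering	pub10	Pv01	47.07	47.07	Phvul.001G214500
published	0	Days to flowering	pub05	Pv01	48.86	48.86	NA
published	0	Days to flowering	pub05	Pv01	49.65	49.65	NA
this_study	0	Halo blight damage score	this_study	Pv02	16.17	16.17	Phvul.002G091900
this_study	1	Seed weight	this_study	Pv02	30.38	30.38	Phvul.002G150600
published	0	Days to flowering	pub04	Pv02	38.07	38.07	NA
published	0	Halo blight damage score	pub07	Pv02	49.08	49.08	Phvul.002G326200
this_study	1	Harvest index (%)	this_study	Pv03	2.16	2.16	Phvul.003G023000
this_study	1	Seed weight	this_study	Pv03	4.40	4.40	Phvul.003G039900
this_study	0	Days to maturity	this_study	Pv03	15.75	15.75	NA
this_study	0	Days to maturity	this_study	Pv03	32.04	32.04	Phvul.003G128400
this_study	0	Harvest index (%)	this_study	Pv03	36.82	36.82	Phvul.003G153100
this_study	0	Days to maturity	this_study	Pv03	36.83	36.83	Phvul.003G153100
published	0	Seed yield	pub06	Pv03	37.60	37.60	Phvul.001G136600
published	0	Days to flowering	pub04	Pv03	40.27	40.27	NA
published	0	Days to flowering	pub04	Pv03	41.09	41.09	NA
published	0	Harvest index (%)	pub06	Pv03	46.70	46.70	Phvul.003G233400
published	0	Harvest index (%)	pub06	Pv03	47.17	47.17	Phvul.003G237900
published	0	Days to flower	pub04	Pv03	47.35	47.35	NA
published	0	Seed yield	pub01	Pv03	49.28	50.33	Phvul.003G253700
published	0	Days to flowering and days to maturity	pub04	Pv03	51.48	51.48	NA
published	0	Days to flowering and days to maturity	pub04	Pv03	52.32	52.32	NA
published	0	Days to flowering and days to maturity	pub04	Pv03	52.60	52.60	NA
published	0	Halo blight damage score	pub07	Pv04	0.55	1.899	Phvul.004G007600
published	0	Days to maturity	pub02	Pv04	1.94	1.94	Phvul.004G011400
this_study	1	Lodging score	this_study	Pv04	2.87	2.87	Phvul.004G025600
published	0	Growth habit indeterminate	pub02	Pv04	3.20	3.20	Phvul.004G027800
companion	0	Halo blight damage score	companion	Pv04	6.79	6.79	Phvul.004G051500
published	0	Days to flowering	pub05	Pv04	16.37	16.37	NA
published	0	Days to flowering	pub05	Pv04	36.88	36.88	NA
published	0	Halo blight damage score	pub07	Pv04	46.20	46.20	Phvul.004G158000
published	0	Days to flowering and days to maturity	pub04	Pv04	46.33	46.33	NA
published	0	Days to flowering and days to maturity	pub04	Pv04	47.06	47.06	NA
this_study	0	Halo blight damage score	this_study	Pv05	13.25	13.25	Phvul.005G074200
published	0	Halo blight damage score	pub07	Pv05	39.00	39.00	Phvul.005G162500
published	0	Root rot damage	pub03	Pv06	0.57	0.57	NA
published	0	Root rot damage	pub03	Pv06	5.75	5.75	NA
published	0	Root rot damage	pub03	Pv06	6.89	6.89	NA
published	0	Root rot damage	pub03	Pv06	8.16	8.16	Phvul.006G017211
published	0	Root rot damage	pub03	Pv06	12.20	12.20	NA
published	0	Root rot damage	pub03	Pv06	17.85	17.85	NA
this_study	0	Plant height (cm)	this_study	Pv06	20.89	20.89	Phvul.006G098300
published	0	Growth habit indeterminate	pub02	Pv06	29.92	29.92	Phvul.006G203400
published	0	Days to flowering	pub05	Pv06	31.60	31.60	NA
this_study	0	Days to maturity	this_study	Pv07	1.15	1.15	Phvul.007G017000
published	0	Growth habit indeterminate	pub02	Pv07	34.12	34.12	Phvul.007G246700
published	0	Lodging score	pub02	Pv07	34.20	34.20	Phvul.007G218900
this_study	1	Lodging score	this_study	Pv07	33.60	34.51	Phvul.007G218900
published	0	Plant height (cm)	pub02	Pv07	34.20	34.20	Phvul.007G218900
published	0	Growth habit indeterminate	pub02	Pv07	34.20	34.20	Phvul.007G218900
this_study	0	Biomass (kg)	this_study	Pv07	35.74	35.74	Phvul.007G233700
published	0	Seed weight	pub02	Pv08	1.10	1.10	Phvul.008G013300
this_study	0	Root rot damage score	this_study	Pv08	1.34	1.34	NA
published	0	Days to flowering	pub05	Pv08	4.93	4.93	NA
published	0	Biomass (kg)	pub09	Pv08	6.86	6.86	Phvul.008G073000
published	0	Biomass (kg)	pub09	Pv08	7.60	7.60	Phvul.008G078200
published	0	Root rot damage	pub03	Pv08	15.26	15.26	NA
published	0	Root rot damage	pub03	Pv08	17.72	17.72	NA
published	0	Days to flowering and days to maturity	pub04	Pv08	24.95	24.95	NA
published	0	Days to flowering	pub05	Pv08	26.40	26.40	NA
published	0	Halo blight damage score	pub07	Pv08	61.34	61.34	Phvul.008G268700
this_study	0	Root rot damage score	this_study	Pv08	61.98	61.98	Phvul.008G277352
this_study	0	Halo blight damage score	this_study	Pv09	5.42	5.42	Phvul.009G022400
this_study	0	Days to maturity	this_study	Pv09	5.85	5.85	NA
published	0	Seed yield	pub06	Pv09	10.00	10.00	Phvul.009G051600
this_study	0	Plant height (cm)	this_study	Pv09	27.98	27.98	Phvul.009G185100
this_study	1	Growth habit	this_study	Pv09	30.93	30.93	Phvul.009G204100
published	0	Biomass (kg)	pub09	Pv10	0.60	0.60	Phvul.010G003600
published	0	Seed weight	pub02	Pv10	2.60	2.60	Phvul.010G017600
published	0	Root rot damage	pub03	Pv10	16.40	16.40	NA
published	0	Root rot damage	pub03	Pv10	19.51	19.51	NA
published	0	Root rot damage	pub03	Pv10	25.44	25.44	NA
published	0	Root rot damage	pub03	Pv10	29.88	29.88	NA
published	0	Biomass (kg)	pub09	Pv10	36.45	36.45	Phvul.010G099100
this_study	0	Halo blight damage score	this_study	Pv10	41.52	41.52	Phvul.010G133101
published	0	Days to flowering	pub10	Pv10	42.50	42.50	Phvul.010G142900
this_study	1	Growth habit	this_study	Pv10	42.79	42.79	Phvul.010G146500
published	0	Biomass (kg)	pub09	Pv11	1.59	1.59	Phvul.011G020500
published	0	Days to flowering	pub04	Pv11	4.02	4.02	NA
published	0	Days to maturity	pub02	Pv11	4.46	4.46	Phvul.011G050300
published	0	Days to flowering	pub04	Pv11	10.66	10.66	NA
companion	0	Days to maturity	companion	Pv11	14.80	14.80	NA
published	0	Root rot damage	pub03	Pv11	26.41	26.41	NA
published	0	Days to flowering	pub04	Pv11	27.27	27.27	NA
published	0	Days to flowering	pub04	Pv11	36.22	36.22	NA
published	0	Root rot damage	pub03	Pv11	41.36	41.36	NA
published	0	Days to maturity	pub02	Pv11	45.09	45.09	Phvul.011G158300
published	0	Days to flowering	pub04	Pv11	45.29	45.29	NA
published	0	Growth habit indeterminate	pub02	Pv11	46.75	46.75	Phvul.011G164800
published	0	Days to flowering	pub04	Pv11	47.30	47.30	NA
published	0	Root rot damage	pub03	Pv11	50.59	50.59	NA
this_study	1	Rust	this_study	Pv11	50.67	50.67	Phvul.011G193100
published	0	Rust	pub11	Pv11	50.67	50.67	Phvul.011G193100
published	0	Biomass (kg)	pub09	Pv11	52.55	52.55	Phvul.011G207500
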