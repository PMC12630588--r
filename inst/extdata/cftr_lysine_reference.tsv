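row	residues	peptide	wt_mean_pct	df508_mean_pct	area_5uak	class_5uak	area_6msm	class_6msm	mapped
K52	52	QIPSVDSADNLSEKL	NA	92.6	93.75	accessible	13.39	accessible	TRUE
K95	95	LGEVTKAVQPL	96.1	77.0	3.51	partially_accessible	35.78	accessible	TRUE
K273	273	VITSEMIENIQSVKAY	61.8	95.0	0.48	inaccessible	6.92	partially_accessible	TRUE
K283	283	CWEEAMEKMIENLRQTEL	98.7	98.9	53.98	accessible	39.15	accessible	TRUE
K370	370	DSLGAINKIQDF	99.8	99.0	41.45	accessible	29.92	accessible	TRUE
K370/K377	370;377	DSGAINKIQDFLQKQEY	99.8	98.9	41.45;39.11	accessible	29.92;36.11	accessible	TRUE
K411	411	NA	NA	NA	NA	NA	NA	NA	FALSE
K420	420	NA	NA	NA	NA	NA	NA	NA	FALSE
K442	442	SLLGTPVLKDINF	99.2	95.7	39.53	accessible	47.84	accessible	TRUE
K464	464	AVAGSTGAGKTSLL	99.7	93.0	9.59	accessible	4.36	partially_accessible	TRUE
K536	536	AEKDNIVLGEGGITL	98.8	94.7	51.94	accessible	26.99	accessible	TRUE
K584	584	GYLDVLTEKEIF	NA	91.9	8.91	accessible	18.03	accessible	TRUE
K1060	1060	ESEGRSPIFTHLVTSLKGLW	99.0	98.5	49.05	accessible	3.15	partially_accessible	TRUE
K1080	1080	FETLFHKAL	99.9	99.7	59.33	accessible	35.59	accessible	TRUE
K1165	1165	KFIDMPTEGKPT	99.5	96.6	19.66	accessible	54.57	accessible	TRUE
K1218	1218	TAKYTEGGNAILENISF	NA	89.3	41.39	accessible	30.56	accessible	TRUE
K1292	1292	GVIPQKVF	NA	94.4	48.20	accessible	3.01	partially_accessible	TRUE
K1302	1302	RKNLDPYEQWSDQEIW	98.4	97.9	26.64	accessible	13.86	accessible	TRUE
K1317	1317	KVADEVGLRSVIEQFPGKLDF	99.7	99.5	37.29	accessible	53.09	accessible	TRUE
K1334	1334	RSVIEQFPGKLDF	99.9	NA	56.92	accessible	49.60	accessible	TRUE
K1420	1420	LVIEENKVRQY	99.3	94.8	51.71	accessible	51.65	accessible	TRUE
K1429	1429	DSIQKLL	99.9	99.5	57.27	accessible	33.64	accessible	TRUE
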