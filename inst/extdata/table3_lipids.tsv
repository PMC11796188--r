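platform	outcome	exposure	mediator	alpha	beta	pct_total_effect	fdr_p	super_pathway
lipid	VPD	bmi10	CER(18:0)	0.044	-0.052	8.73	0.009	Sphingolipid
lipid	VPD	bmi10	LCER(14:0)	-0.032	0.065	7.86	0.03	Sphingolipid
lipid	VPD	bmi10	LPC(18:1)	-0.038	0.011	1.59	0.08	Phospholipid
lipid	VPD	bmi10	PC(18:1/18:1)	-0.040	0.064	9.72	0.009	Phospholipid
lipid	VPD	bmi18	CER(18:0)	0.030	-0.059	10.07	0.01	Sphingolipid
lipid	VPD	bmi18	LCER(14:0)	-0.027	0.053	8.14	0.01	Sphingolipid
lipid	VPD	bmi18	PC(18:1/18:1)	-0.021	0.064	7.66	0.04	Phospholipid
lipid	VPD	bmi18	TAG56:5-FA22:5	0.027	0.106	-16.14	0.01	Neutral complex lipid
lipid	VPD	bmi18	TAG52:2-FA16:0	0.031	-0.062	10.79	0.008	Neutral complex lipid
lipid	NDV	bmi10	CER(18:0)	0.044	0.044	8.21	0.01	Sphingolipid
lipid	NDV	bmi10	LPC(18:1)	-0.038	-0.038	6.09	0.01	Phospholipid
lipid	NDV	bmi10	PC(18:1/18:1)	-0.040	-0.071	11.92	0.01	Phospholipid
lipid	NDV	bmi18	CER(18:0)	0.030	0.039	5.65	0.01	Sphingolipid
lipid	NDV	bmi18	DAG(16:0/18:1)	0.037	0.062	11.02	0.002	Neutral complex lipid
lipid	NDV	bmi18	PC(18:1/18:1)	-0.021	-0.080	8.13	0.04	Phospholipid
lipid	NDV	bmi18	TAG49:2-FA18:2	0.023	-0.073	-8.06	0.04	Neutral complex lipid
lipid	NDV	bmi18	TAG56:6-FA22:5	0.022	-0.128	-13.82	0.04	Neutral complex lipid
lipid	NDV	bmi18	TAG56:6-FA20:4	0.023	0.059	6.57	0.04	Neutral complex lipid
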