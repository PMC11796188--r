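platform	outcome	exposure	mediator	alpha	beta	pct_total_effect	fdr_p	super_pathway
metabolite	VPD	bmi10	Glutamate	0.036	-0.049	6.65	0.06	Amino Acid
metabolite	VPD	bmi10	beta-cryptoxanthin	-0.036	0.030	4.09	0.06	Cofactors/Vitamins
metabolite	VPD	bmi10	Cortolone glucuronide (1)	0.033	-0.016	2.03	0.07	Lipids (2)
metabolite	VPD	bmi10	Phytanate	-0.034	0.020	2.58	0.06	Xenobiotics
metabolite	VPD	bmi18	Glutamate	0.043	-0.039	9.29	0.008	Amino Acids
metabolite	VPD	bmi18	beta-cryptoxanthin	-0.040	0.028	6.34	0.04	Cofactors/Vitamins
metabolite	NDV	bmi10	Citrulline	-0.031	-0.012	1.56	0.08	Amino Acids
metabolite	NDV	bmi10	Phytanate	-0.034	-0.050	7.10	0.05	Xenobiotics
metabolite	NDV	bmi10	Mannose	0.050	0.047	10.11	0.004	Carbohydrates
metabolite	NDV	bmi10	Glycerol	0.029	0.039	4.72	0.09	Lipids (1)
metabolite	NDV	bmi10	Isovalerylglycine	-0.042	-0.035	6.30	0.02	Amino Acids
metabolite	NDV	bmi10	Cysteinylglycine disulfide	0.048	0.022	4.48	0.03	Amino Acids
metabolite	NDV	bmi10	Cortolone glucuronide (1)	0.033	0.051	7.10	0.07	Lipids (2)
metabolite	NDV	bmi10	Hydroxyasparagine	0.038	0.047	7.51	0.04	Amino Acids
metabolite	NDV	bmi10	2,6-dihydroxybenzoic acid	-0.029	-0.011	1.35	0.08	Xenobiotics
metabolite	NDV	bmi10	Tetrahydrocortisone glucuronide (5)	0.032	-0.049	-6.65	0.08	Lipids (2)
metabolite	NDV	bmi18	Mannose	0.033	0.050	8.01	0.006	Carbohydrates
metabolite	NDV	bmi18	Urate	0.034	0.022	3.56	0.02	Nucleotide
metabolite	NDV	bmi18	Glycerol	0.024	0.024	2.76	0.08	Lipids (1)
metabolite	NDV	bmi18	N2,N5-diacetylornithine	-0.023	-0.035	3.83	0.09	Amino Acids
metabolite	NDV	bmi18	2,6-dihydroxybenzoic acid	-0.023	-0.003	0.30	0.08	Xenobiotics
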