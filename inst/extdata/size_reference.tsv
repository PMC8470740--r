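# Published ensemble-average size estimates for the four peptides simulated
# with Amber ff99SB-ILDN+TIP4P-D (A99) and CHARMM36m (C36): radius of
# gyration and end-to-end distance in nm with block-averaging errors, plus
# experimental reference values where available (SAXS Rg for Stath, FRET Ree
# for Tau1). Units: nm.
peptide	observable	a99_mean	a99_err	c36_mean	c36_err	exp_mean	exp_err
Tau1	rg	1.17	0.01	1.12	0.01	NA	NA
Tau1	ree	3.44	0.04	2.88	0.07	3.17	NA
Tau2	rg	1.29	0.03	1.06	0.10	NA	NA
Tau2	ree	3.27	0.17	2.10	0.32	NA	NA
bCPP	rg	1.43	0.03	1.08	0.02	NA	NA
bCPP	ree	3.09	0.15	1.65	0.10	NA	NA
Stath	rg	1.73	0.09	1.41	0.04	1.93	0.2
Stath	ree	4.05	0.17	2.74	0.20	NA	NA
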