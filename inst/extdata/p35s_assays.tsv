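assay_id	kind	role	name	sequence	reported_start	reported_end	reported_amplicon	mismatch_mask	size_consistent
M1	taqman	forward	35S-1	GCTCCTACAAATGCCATCA	7190	7208	195	3	TRUE
M1	taqman	reverse	35S-2	GATAGTGGGATTGTGCGTCA	7365	7384	195		TRUE
M1	taqman	probe	35S core	TCTCCACTGACGTAAGGGATGACGCA	7346	7371	195	1,2	TRUE
M2	taqman	forward	35S-F3	CGACAGTGGTCCCAAAGA	7248	7265	74	8	TRUE
M2	taqman	reverse	35S-R3	AAGACGTGGTTGGAACGTCTTC	7300	7321	74		TRUE
M2	taqman	probe	35S-P	TGGACCCCCACCCACGAGGAGCATC	7266	7290	74	21	TRUE
M3	taqman	forward	P35S 1-5'	ATTGATGTGATATCTCCACTGACGT	7334	7358	101	11,13,14	TRUE
M3	taqman	reverse	P35S 2-3'	CCTCTCCAAATGAAATGAACTTCCT	7410	7434	101		TRUE
M3	taqman	probe	P35S-Taq	CCCACTATCCTTCGCAAGACCCTTCCT	7376	7402	101	4,22	TRUE
M4	taqman	forward	sF	CGTCTTCAAAGCAAGTGGATTG	7316	7337	79	21	TRUE
M4	taqman	reverse	sR	TCTTGCGAAGGATAGTGGGATT	7373	7394	79		TRUE
M4	taqman	probe	P-35S_3-P	TCTCCACTGACGTAAGGGATGACGCA	7346	7371	79	1,2	TRUE
M5	taqman	forward	35SFZ1	CCGACAGTGGTCCCAAAGATGGAC	7247	7270	162	9	TRUE
M5	taqman	reverse	35SFZ2	ATATAGAGGAAGGGTCTTGCGAAGG	7384	7408	162	12	TRUE
M5	taqman	probe	35S core	TCTCCACTGACGTAAGGGATGACGCA	7346	7371	162	1,2	TRUE
M6	taqman	forward	P-35S_4-L	GACGTAAGGGATGACGCACAA	7354	7374	81		TRUE
M6	taqman	reverse	P-35S_4-R	CCTCTCCAAATGAAATGAACTTCCT	7410	7434	81		TRUE
M6	taqman	probe	P-35S_4-P	CCCACTATCCTTCGCAAGACCCTTC	7376	7400	81	9,22	TRUE
M7	taqman	forward	35S-promoter.for	GACATTGCGATAAAGGAAAGGC	7205	7226	68	1,2	TRUE
M7	taqman	reverse	35S-promoter.rev	GGGTCCATCTTTGGGACCA	7254	7272	68	17	TRUE
M7	taqman	probe	35Spromoter-specific	ATCGTTGAAGATGCCTCTGCCGACA	7228	7252	68	4,7,19	TRUE
M8	taqman	forward	35SF	CCTACAAATGCCATCATTGCG	7193	7213	205		TRUE
M8	taqman	reverse	35SR	GGGTCTTGCGAAGGATAGTG	7378	7397	205	1	TRUE
M8	taqman	probe	35S Wolf	CAAAGATGGACCCCCACCCACG	7260	7281	205		TRUE
M9	taqman	forward	3-16f	CGTCTTCAAAGCAAGTGGAT	7316	7335	105		FALSE
M9	taqman	reverse	3-100r	GAAGGGTCTTGCGAAGGA	7383	7400	105	4	FALSE
M9	taqman	probe	3-67t	ACGCACAATCCCACTA	7367	7382	105		FALSE
M10	microarray	forward	P-35S_31-L	AGACTGGCGAACAGTTCATACAGA	6956	6979	188		FALSE
M10	microarray	reverse	P-35S_31-R	CAATGGAATCCGAGGAGGT	7124	7142	188		FALSE
M10	microarray	probe	P-35S_31-P	TGCTCCACCATGTTGACGAAG	7011	7031	188	3,11	FALSE
M11	microarray	forward	P-35S-AF	AAGATGCCTCTGCCGACAGT	7235	7254	142		TRUE
M11	microarray	reverse	P-35S-AR	GATTGTGCGTCATCCCTTAC	7357	7376	142		TRUE
M11	microarray	probe	P-35S	GAACGTCTTCTTTTTCCACGATGCTCCTCG	7280	7309	142		TRUE
M12	taqman	forward	P180-F	GCCTCTGCCGACAGTGGT	7240	7257	82	16	TRUE
M12	taqman	reverse	P180-R	AAGACGTGGTTGGAACGTCTTC	7300	7321	82		TRUE
M12	taqman	probe	P180-P	CAAAGATGGACCCCCACCCACG	7260	7281	82		TRUE
M13	taqman	forward	P-35S-F	GACGTAAGGGATGACGCACAA	7354	7374	81		TRUE
M13	taqman	reverse	P-35S-R	CCTCTCCAAATGAAATGAACTTCCT	7410	7434	81	1	TRUE
M13	taqman	probe	P-35S-P	CCCACTATCCTTCGCAAGACCCTTCC	7376	7401	81	4	TRUE
M14	taqman	forward	p35S-cf3	CCACGTCTTCAAAGCAAGTGG	7313	7333	123		TRUE
M14	taqman	reverse	p35S-cr4	TCCTCTCCAAATGAAATGAACTTCC	7411	7435	123		TRUE
M14	taqman	probe	35S core	TCTCCACTGACGTAAGGGATGACGCA	7346	7371	123	1,2	TRUE
M15	conventional	forward	35S-F	GCTCCTACAAATGCCATCATTGC	7190	7212	195	3	TRUE
M15	conventional	reverse	35S-R	GATAGTGGGATTGTGCGTCATCCC	7361	7384	195		TRUE
M16	conventional	forward	35S-F2	TCATCCCTTACGTCAGTGGAG	7347	7367	165	21	TRUE
M16	conventional	reverse	35S-R2	CCATCATTGCGATAAAGGAAA	7203	7223	165		TRUE
M17	conventional	forward	35SFZMP1	CCGACAGTGGTCCCAAAGATG	7247	7267	158	9	TRUE
M17	conventional	reverse	35SFZMP2	AGAGGAAGGGTCTTGCGAAGG	7384	7404	158	8	TRUE
M18	conventional	forward	SP1 F	TTGCTTTGAAGACGTGGTTG	7310	7329	196		TRUE
M18	conventional	reverse	SP1 R	ATTCCATTGCCCAGCTATCT	7134	7153	196	18	TRUE
M19	conventional	forward	35S3F	GCCATCATTGCGATAAAGGAAAGG	7202	7225	173		TRUE
M19	conventional	reverse	35S6R	TTGTGCGTCATCCCTTACGTCAGTG	7350	7374	173		TRUE
M20	conventional	forward	CM01	CACTACAAATGCCATCATTGCGATA	7192	7216	220	1,2	TRUE
M20	conventional	reverse	CM02	CTTATATAGAGGAAGGGTCTTGCGA	7387	7411	220	15	TRUE
M21	conventional	forward	35S-A	AAGGGTCTTGCGAAGGATAG	7380	7399	227	3	TRUE
M21	conventional	reverse	35S-B	AGTGGAAAAGGAAGGTGGCT	7173	7192	227	4,20	TRUE
M22	conventional	forward	35S F	CCTACAAATGCCATCATTGCG	7193	7213	207		FALSE
M22	conventional	reverse	35S R	GGGTCTTGCGAAGGATAGTG	7378	7397	207	1	FALSE
M23	conventional	forward	35S-111 F	GTGGTCCCAAAGATGGACCC	7253	7272	111	3	TRUE
M23	conventional	reverse	35S-111 R	CCCTTACGTCAGTGGAGATATCACA	7339	7363	111	23	TRUE
M24	nested	forward	35SA	AAGGGTCTTGCGAAGGATAG	7380	7399	149	3	FALSE
M24	nested	reverse	35SB	AGTGGAAAAGGAAGGTGGCT	7173	7192	149	4,20	FALSE
M24	nested	reverse	35SC	ACAGTGGTCCCAAAGATGGA	7250	7269	149	6	FALSE
M25	taqman	forward	35SEF	CATCATTGCGATAAAGGAAAGGC	7204	7226	125		TRUE
M25	taqman	reverse	35SER	TGCTTTGAAGACGTGGTTGGA	7308	7328	125		TRUE
M25	taqman	probe	35SEP	TCGTGGGTGGGGGTC	7247	7268	125		TRUE
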