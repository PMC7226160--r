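anchor	offset	ortholog_family	strand
BSUB_trmFO	1	mnmG	+
BSUB_trmFO	-1	rsmG	-
BSUB_trmFO	2	jag	+
BSUB_trmFO	-2	spoIIIJ	-
BSUB_trmFO	3	rnpA	+
BSUB_trmFO	-3	parB	-
ALAID_trmFO_1	1	mnmG	+
ALAID_trmFO_1	-1	rsmG	-
ALAID_trmFO_1	2	jag	+
ALAID_trmFO_1	-2	spoIIIJ	-
ALAID_trmFO_1	3	rnpA	+
ALAID_trmFO_1	-3	dnaA	-
ALAID_trmFO_2	1	mnmG	+
ALAID_trmFO_2	-1	rsmG	-
ALAID_trmFO_2	2	jag	+
ALAID_trmFO_2	-2	dnaA	-
ALAID_trmFO_2	3	ftsH	+
ALAID_trmFO_2	-3	secA	-
SCITR_trmFO	1	mnmG	+
SCITR_trmFO	-1	rsmG	-
SCITR_trmFO	2	jag	+
SCITR_trmFO	-2	parB	-
MFLOR_trmFO	1	mnmG	+
MFLOR_trmFO	-1	rsmG	-
MFLOR_trmFO	2	jag	+
MFLOR_trmFO	-2	spoIIIJ	-
MFLOR_trmFO	3	rnpA	+
MFLOR_trmFO	-3	parB	-
MYEAT_trmFO	1	mnmG	+
MYEAT_trmFO	-1	rsmG	-
MYEAT_trmFO	2	jag	+
MYEAT_trmFO	-2	spoIIIJ	-
MYEAT_trmFO	3	rnpA	+
MYEAT_trmFO	-3	ftsH	-
MPUTR_trmFO	1	mnmG	+
MPUTR_trmFO	-1	rsmG	-
MPUTR_trmFO	2	jag	+
MPUTR_trmFO	-2	spoIIIJ	-
MPUTR_trmFO	3	rnpA	+
MPUTR_trmFO	-3	secA	-
MCAP_0476	1	rpsB	+
MCAP_0476	-1	tsf	-
MCAP_0476	2	pyrH	+
MCAP_0476	-2	frr	-
MCAP_0476	3	uppS	+
MCAP_0476	-3	cdsA	-
SCITR_rlmFO	1	rpsB	+
SCITR_rlmFO	-1	tsf	-
SCITR_rlmFO	2	pyrH	+
SCITR_rlmFO	-2	frr	-
SCITR_rlmFO	3	uppS	+
SCITR_rlmFO	-3	cdsA	-
MFLOR_rlmFO	1	rpsB	+
MFLOR_rlmFO	-1	tsf	-
MFLOR_rlmFO	2	pyrH	+
MFLOR_rlmFO	-2	frr	-
MFLOR_rlmFO	3	uppS	+
MFLOR_rlmFO	-3	dnaJ	-
MAURI_rlmFO	1	rpsB	+
MAURI_rlmFO	-1	tsf	-
MAURI_rlmFO	2	pyrH	+
MAURI_rlmFO	-2	frr	-
MAURI_rlmFO	3	uppS	+
MAURI_rlmFO	-3	cdsA	-
MYEAT_rlmFO	1	rpsB	+
MYEAT_rlmFO	-1	tsf	-
MYEAT_rlmFO	2	pyrH	+
MYEAT_rlmFO	-2	frr	-
MYEAT_rlmFO	3	uppS	+
MYEAT_rlmFO	-3	cdsA	-
MPUTR_rlmFO	1	rpsB	+
MPUTR_rlmFO	-1	tsf	-
MPUTR_rlmFO	2	pyrH	+
MPUTR_rlmFO	-2	frr	-
MPUTR_rlmFO	3	uppS	+
MPUTR_rlmFO	-3	dnaJ	-
MMYCO_rlmFO	1	rpsB	+
MMYCO_rlmFO	-1	tsf	-
MMYCO_rlmFO	2	pyrH	+
MMYCO_rlmFO	-2	frr	-
MMYCO_rlmFO	3	uppS	+
MMYCO_rlmFO	-3	cdsA	-
MCAPR_rlmFO	1	rpsB	+
MCAPR_rlmFO	-1	tsf	-
MCAPR_rlmFO	2	pyrH	+
MCAPR_rlmFO	-2	frr	-
MCAPR_rlmFO	3	uppS	+
MCAPR_rlmFO	-3	cdsA	-
MCAP_0613	1	folT	+
MCAP_0613	-1	ecfA	-
MCAP_0613	2	glpK	+
MCAP_0613	-2	oppA	-
MCAP_0613	3	gatA	+
MCAP_0613	-3	pdhA	-
MAURI_trmFO_like	1	folT	+
MAURI_trmFO_like	-1	ecfT	-
MAURI_trmFO_like	2	ldh	+
MAURI_trmFO_like	-2	oppB	-
MAURI_trmFO_like	3	gatB	+
MAURI_trmFO_like	-3	nox	-
MYEAT_trmFO_like	1	folT	+
MYEAT_trmFO_like	-1	ecfA	-
MYEAT_trmFO_like	2	ecfT	+
MYEAT_trmFO_like	-2	oppC	-
MYEAT_trmFO_like	3	pdhB	+
MYEAT_trmFO_like	-3	ackA	-
MPUTR_trmFO_like	1	folT	+
MPUTR_trmFO_like	-1	glpK	-
MPUTR_trmFO_like	2	ldh	+
MPUTR_trmFO_like	-2	oppD	-
MPUTR_trmFO_like	3	pta	+
MPUTR_trmFO_like	-3	adk	-
MAGAL_trmFO_like	1	folT	+
MAGAL_trmFO_like	-1	vpmA	-
MAGAL_trmFO_like	2	tnpA	+
MAGAL_trmFO_like	-2	oppF	-
MAGAL_trmFO_like	3	gapA	+
MAGAL_trmFO_like	-3	pgk	-
MBOVI_trmFO_like	1	folT	+
MBOVI_trmFO_like	-1	vspA	-
MBOVI_trmFO_like	2	tnpA	+
MBOVI_trmFO_like	-2	oppF	-
MBOVI_trmFO_like	3	gapA	+
MBOVI_trmFO_like	-3	eno	-
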