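# Reference cohort: the 67 immunome TAAs with Mann-Whitney p < 0.01
# (healthy donors n=7 vs sCRC patients n=50). None of these TAAs were
# positive in any healthy donor. Columns: Mann-Whitney p-value, number of
# sCRC samples with a positive call (out of 50), median fold change over
# sCRC cases, and percent of sCRC cases with FC > 1.
taa_id	p_value	n_positive	n_group	median_fc	pct_cases_fc_gt1
TEX11	0.0005	8	50	2.6	90
GORASP2	0.0007	2	50	3.1	82
C9orf80	0.0007	3	50	3.9	92
HMOX2	0.0008	13	50	3.0	92
KIF9	0.0008	14	50	2.7	92
ICAM2	0.0012	16	50	2.4	94
MARCKSL1	0.0012	10	50	2.4	88
RB1	0.0012	2	50	2.6	92
SPP1	0.0012	3	50	2.8	86
STC2	0.0013	10	50	2.0	84
BHMT2	0.0014	10	50	2.2	86
D21S2056E	0.0016	10	50	2.2	84
DLAT	0.0016	2	50	2.3	86
CKMT1B	0.0017	27	50	2.6	86
GTF2H1	0.0017	8	50	2.3	82
ALDOA	0.0019	8	50	2.0	88
COX11	0.0020	14	50	2.4	88
RPL11	0.0020	2	50	2.4	86
ASB3	0.0020	8	50	2.3	84
PRCP	0.0024	21	50	1.9	86
PDEF	0.0024	10	50	2.2	86
ANP32A	0.0024	2	50	2.3	82
GNAI3	0.0026	5	50	2.5	86
HBG1	0.0026	2	50	3.5	84
ARHI	0.0028	11	50	1.9	86
RCV1	0.0028	3	50	2.9	86
RAB8A	0.0028	5	50	2.4	84
GDEP	0.0030	11	50	2.2	82
PLAC1	0.0030	7	50	2.0	84
HSD17B3	0.0030	2	50	2.3	80
SH3BP1	0.0033	3	50	2.0	84
USP5	0.0033	2	50	2.1	82
TCEAL1	0.0033	5	50	2.5	84
KPNA6	0.0035	18	50	2.3	84
Progranulin	0.0038	4	50	1.8	86
CHODL	0.0038	4	50	2.2	86
KCNE2	0.0041	13	50	2.0	82
SERPINA5	0.0041	5	50	2.2	80
SLCO4A1	0.0041	4	50	2.5	80
SDPR	0.0041	10	50	1.8	86
JUP	0.0041	3	50	2.5	82
FRK	0.0041	6	50	2.1	84
DDX39	0.0044	2	50	2.1	80
PSAP	0.0048	2	50	2.1	84
SCARB1	0.0048	2	50	2.6	84
AMY2A	0.0052	9	50	2.1	84
BECN1	0.0056	16	50	2.0	84
ST14	0.0056	16	50	1.7	80
LDHB	0.0056	8	50	2.3	84
SNX10	0.0056	2	50	2.1	82
PSTPIP1	0.0060	17	50	2.1	84
SLC6A1	0.0065	6	50	2.0	78
HM13	0.0070	10	50	1.7	84
RHOH	0.0070	7	50	1.9	82
KIF22	0.0075	5	50	2.4	78
SYTL1	0.0075	4	50	2.1	80
Mage3	0.0075	10	50	1.9	82
HIST1H3D	0.0075	4	50	2.3	82
RWDD1	0.0080	9	50	2.1	80
RILP	0.0080	6	50	2.0	76
RPL35	0.0080	4	50	1.9	82
PLAGL1	0.0086	21	50	1.6	82
DDX56	0.0086	9	50	1.7	84
CTNNA1	0.0086	9	50	2.2	82
BET1	0.0086	4	50	2.0	78
HLA-DOB	0.0093	28	50	1.6	80
HSPC047	0.0093	4	50	1.9	80
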