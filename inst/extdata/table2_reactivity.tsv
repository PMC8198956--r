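# Reference cohort: per-sample positive autoantibody counts against 2023
# unique TAA features (57 plasma samples: 50 sCRC, 7 healthy donors).
# Kept verbatim as published. Note: narrative summaries elsewhere quote the
# per-sample range as 48 (2%) to 1288 (64%), but the tabulated maximum is
# 1310 (65%, sample 37); the table is not corrected.
sample_id	diagnosis	n_positive	pct_positive
1	sCRC	862	43
2	sCRC	846	42
3	sCRC	822	41
4	sCRC	191	9
5	sCRC	110	5
6	sCRC	466	23
7	sCRC	609	30
8	sCRC	832	41
9	sCRC	704	35
10	sCRC	285	14
11	sCRC	497	25
12	sCRC	851	42
13	sCRC	249	12
14	sCRC	717	35
15	sCRC	227	11
16	sCRC	646	32
17	sCRC	1040	51
18	sCRC	447	22
19	sCRC	593	29
20	sCRC	174	9
21	sCRC	1228	61
22	sCRC	1288	64
23	sCRC	471	23
24	sCRC	1225	61
25	sCRC	615	30
26	sCRC	458	23
27	sCRC	521	26
28	sCRC	864	43
29	sCRC	266	13
30	sCRC	1150	57
31	sCRC	813	40
32	sCRC	608	30
33	sCRC	671	33
34	sCRC	1141	56
35	sCRC	700	35
36	sCRC	381	19
37	sCRC	1310	65
38	sCRC	217	11
39	sCRC	327	16
40	sCRC	562	28
41	sCRC	541	27
42	sCRC	755	37
43	sCRC	557	28
44	sCRC	415	21
45	sCRC	720	36
46	sCRC	93	5
47	sCRC	363	18
48	sCRC	505	25
49	sCRC	48	2
50	sCRC	381	19
51	Healthy donor	715	35
52	Healthy donor	398	20
53	Healthy donor	880	43
54	Healthy donor	1149	57
55	Healthy donor	229	11
56	Healthy donor	278	14
57	Healthy donor	345	17
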