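feature_id	WT_1	WT_2	WT_3	KO_1	KO_2	KO_3
G0001	18	12	28	24	19	26
G0002	17	16	13	67	58	89
G0009	25	17	17	23	23	24
G0011	11	15	22	19	13	24
G0013	12	15	13	33	21	18
G0018	26	20	17	22	20	19
G0021	17	19	12	25	23	19
G0027	18	27	13	18	14	11
G0029	11	21	18	23	26	21
G0030	17	19	21	12	17	14
G0031	20	27	20	10	18	19
G0036	16	26	20	17	20	14
G0039	14	18	19	14	24	28
G0040	18	22	20	20	15	20
G0042	19	11	15	71	70	88
G0044	23	21	19	17	17	9
G0048	21	24	26	17	28	21
G0050	21	30	21	30	21	36
G0051	16	19	14	16	21	22
G0052	15	24	20	17	13	23
G0054	15	14	18	20	18	21
G0055	30	34	15	16	20	23
G0056	20	18	24	22	21	18
G0057	17	14	21	24	29	31
G0058	18	22	18	17	15	13
G0063	13	23	14	30	21	33
G0069	16	24	13	20	23	31
G0070	19	12	17	25	19	10
G0072	26	19	12	24	24	20
G0074	17	15	21	15	15	23
G0077	22	16	15	25	22	20
G0080	19	17	21	20	19	16
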