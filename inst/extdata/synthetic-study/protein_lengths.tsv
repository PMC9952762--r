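protein_id	length
G0001	447
G0002	951
G0009	455
G0011	650
G0013	600
G0018	564
G0021	124
G0027	248
G0029	271
G0030	822
G0031	477
G0036	875
G0039	816
G0040	769
G0042	546
G0044	689
G0048	999
G0050	539
G0051	841
G0052	819
G0054	654
G0055	399
G0056	142
G0057	686
G0058	626
G0063	211
G0069	571
G0070	903
G0072	261
G0074	866
G0077	337
G0080	917
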