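module_01		G0002	G0003	G0004	G0006	G0022	G0042
decoy_01		G0005	G0007	G0010	G0017	G0026	G0076
decoy_02		G0022	G0024	G0026	G0034	G0036	G0069
decoy_03		G0013	G0018	G0022	G0028	G0035	G0080
decoy_04		G0006	G0008	G0022	G0039	G0052	G0063
decoy_05		G0022	G0025	G0030	G0065	G0075	M004
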