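contrast	lineage_x	lineage_y	a_x	a_y	a_s	g0
mcmt	pine_mcmt	spruce_mcmt	50	121	5	9891
ahm_spruce_vs_pine_mcmt	pine_mcmt	spruce_ahm	50	23	1	9891
ahm_pine_vs_spruce_mcmt	pine_ahm	spruce_mcmt	25	121	0	9891
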