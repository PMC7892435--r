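marker	dist_cM	delta
D1S212	4.92	0.326
D1S2659	3.27	0.628
D1S218	0.73	0.945
D1S2790	1.00	0.899
D1S1165	2.43	0.741
D1S2815	2.53	0.731
D1S196	7.35	0.470
D1S460	54.8	0.086
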