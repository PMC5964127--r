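length_min	length_max	agg_count	risk_percent	source
55	59	0	2.6	Yrigollen et al. 2012
69	69	0	22.9	Yrigollen et al. 2012
75	75	0	77	Yrigollen et al. 2012
95	100	0	100	Yrigollen et al. 2012
69	69	2	0.5	Yrigollen et al. 2012
75	75	2	12	Yrigollen et al. 2012
80	84	2	30	Yrigollen et al. 2012 (approximate, ~30%)
85	89	2	60	Yrigollen et al. 2012
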