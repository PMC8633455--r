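type	size	energy
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
bulge	1	3.8
bulge	2	2.8
bulge	3	3.2
bulge	4	3.6
bulge	5	4.0
bulge	6	4.4
internal	2	4.1
internal	3	4.5
internal	4	4.9
internal	5	5.3
internal	6	5.7
multiloop_closing	NA	4.6
multiloop_branch	NA	0.4
multiloop_unpaired	NA	0.1
extrapolation_coef	NA	1.078
max_interior	NA	30
min_hairpin	NA	3
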