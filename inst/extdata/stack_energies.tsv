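pair	AU	UA	GC	CG	GU	UG
AU	-1.2	-1.2	-2.1	-2.1	-1.0	-1.0
UA	-1.2	-1.2	-2.1	-2.1	-1.0	-1.0
GC	-2.1	-2.1	-3.0	-3.0	-1.9	-1.9
CG	-2.1	-2.1	-3.0	-3.0	-1.9	-1.9
GU	-1.0	-1.0	-1.9	-1.9	-0.8	-0.8
UG	-1.0	-1.0	-1.9	-1.9	-0.8	-0.8
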