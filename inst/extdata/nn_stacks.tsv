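pair	CG	GC	GU	UG	AU	UA
CG	-2.9	-2.9	-2.0	-2.0	-2.3	-2.3
GC	-2.9	-2.9	-2.0	-2.0	-2.3	-2.3
GU	-2.0	-2.0	-1.1	-1.1	-1.4	-1.4
UG	-2.0	-2.0	-1.1	-1.1	-1.4	-1.4
AU	-2.3	-2.3	-1.4	-1.4	-1.7	-1.7
UA	-2.3	-2.3	-1.4	-1.4	-1.7	-1.7
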