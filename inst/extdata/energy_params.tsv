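param	value
hairpin_a	4.0
hairpin_b	0.05
loop_a	2.0
loop_b	0.4
multi_a	3.4
multi_b	0.4
multi_c	0.1
max_interior	30
min_loop	3
duplex_init	4.1
end_penalty	0.45
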