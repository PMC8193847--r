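n_xos	n_pairs
0	4
1	81
2	31
3	8
4	1
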