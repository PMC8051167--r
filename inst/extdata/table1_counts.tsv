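ordinal	n_patterns	n_tfbs	n_ss
1	385	294	137
2	147	121	41
3	173	150	58
4	88	67	28
5	121	96	42
6	84	63	30
7	20	14	6
8	8	3	4
9	18	16	5
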