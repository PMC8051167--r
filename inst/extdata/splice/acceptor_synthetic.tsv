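Pos	A	C	G	T
-13	0.09	0.31	0.12	0.48
-12	0.08	0.33	0.10	0.49
-11	0.07	0.32	0.11	0.50
-10	0.08	0.35	0.09	0.48
-9	0.09	0.34	0.10	0.47
-8	0.07	0.36	0.09	0.48
-7	0.08	0.33	0.10	0.49
-6	0.06	0.38	0.09	0.47
-5	0.08	0.36	0.10	0.46
-4	0.25	0.27	0.24	0.24
-3	0.04	0.75	0.01	0.20
-2	1.00	0.00	0.00	0.00
-1	0.00	0.00	1.00	0.00
1	0.25	0.15	0.50	0.10
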