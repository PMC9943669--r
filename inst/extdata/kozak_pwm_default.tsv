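offset	A	C	G	T
-6	0.22	0.28	0.34	0.16
-5	0.18	0.36	0.28	0.18
-4	0.20	0.34	0.26	0.20
-3	0.42	0.12	0.38	0.08
-2	0.20	0.38	0.24	0.18
-1	0.18	0.40	0.26	0.16
0	0.25	0.25	0.25	0.25
1	0.25	0.25	0.25	0.25
2	0.25	0.25	0.25	0.25
3	0.22	0.20	0.44	0.14
4	0.24	0.28	0.28	0.20
5	0.24	0.26	0.28	0.22
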