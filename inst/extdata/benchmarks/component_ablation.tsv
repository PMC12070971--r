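row	occlusion_loss	weconv	opam	ls_head	ap50_95	flops_g	params_m
1	0	0	0	0	82.14	28.6	11.2
2	1	0	0	0	82.49	28.6	11.2
3	1	1	0	0	83.44	26.8	10.4
4	1	0	1	0	83.64	33.1	11.4
5	1	0	0	1	83.38	26.3	9.5
6	1	1	1	0	83.73	31.4	10.7
7	1	1	0	1	83.66	24.5	8.8
8	1	0	1	1	83.68	30.4	9.8
9	1	1	1	1	84.27	28.8	9.0
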