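middle_channel	ap50_95	flops_g	params_m
64	82.88	22.1	9.2
128	83.19	26.3	9.5
256	83.33	42.1	10.5
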