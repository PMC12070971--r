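dataset	images	instances	train	val	test
ChickenFlow	4718	90717	3309	464	945
GooseDetect	2660	98111	2147	256	257
SheepCounter	1727	55435	1203	350	174
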