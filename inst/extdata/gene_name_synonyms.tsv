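raw	normalized
rrn16S	rrn16
rrn23S	rrn23
rrn4.5S	rrn4.5
rrn5S	rrn5
16S	rrn16
23S	rrn23
4.5S	rrn4.5
5S	rrn5
psbA1	psbA
rps12A	rps12
rps12B	rps12
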