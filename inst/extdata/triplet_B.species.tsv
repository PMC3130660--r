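b1	uB1
b2	uB2
b3	sp1
b4	uB4
b5	uB5
b6	uB6
b7	sp2
b8	sp3
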