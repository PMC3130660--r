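a1	uA1
a2	sp1
a3	sp2
a4	uA4
a5	sp3
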