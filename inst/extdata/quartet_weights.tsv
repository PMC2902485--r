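# leaf1	leaf2	weight
a	b	1
c	d	1
a	c	3
b	d	3
a	d	0
b	c	0
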