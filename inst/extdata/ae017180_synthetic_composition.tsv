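base	count
A	745662
C	1161402
G	1161402
T	745662
N	0
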