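condition	n_4mC	n_6mA
control	43685	2000
1G	42744	1957
10G	42830	2013
100G	40090	1882
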