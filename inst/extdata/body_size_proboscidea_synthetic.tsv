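time	value
60	5
56	17
46	250
37	900
33	2500
27	3600
20	5000
10	7000
5	8000
0	9500
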