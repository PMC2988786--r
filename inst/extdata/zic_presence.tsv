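Porifera	0
Ctenophora	0
Placozoa	1
Cnidaria	1
Bilateria	1
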