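# example whitelist
ENA	EF151088
ENA	EF151123
ENA	EF153103
ENA	CP000155
PDB	1J4N
PDB	1FX8
PDB	1RC2
PDB	1EWK
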