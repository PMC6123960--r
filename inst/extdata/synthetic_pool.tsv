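species	morphs
syn_sp02	D
syn_sp03	D,C
syn_sp04	C
syn_sp05	C,D
syn_sp09	A
syn_sp10	B
syn_sp15	C
syn_sp17	D
syn_sp24	D,C
syn_sp27	D
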