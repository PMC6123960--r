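species	state
syn_sp01	D
syn_sp02	D
syn_sp03	D,C
syn_sp04	C
syn_sp05	C,D
syn_sp06	C
syn_sp07	C
syn_sp08	C
syn_sp09	A
syn_sp10	B
syn_sp11	B
syn_sp12	B
syn_sp13	B
syn_sp14	C
syn_sp15	C
syn_sp16	D
syn_sp17	D
syn_sp18	D
syn_sp19	D
syn_sp20	C
syn_sp21	C
syn_sp22	D
syn_sp23	C
syn_sp24	D,C
syn_sp25	C
syn_sp26	B
syn_sp27	D
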