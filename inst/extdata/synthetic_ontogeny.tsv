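species	state
syn_sp01	no_loss
syn_sp02	no_loss
syn_sp03	no_loss
syn_sp04	no_loss
syn_sp05	no_loss
syn_sp06	no_loss
syn_sp07	no_loss
syn_sp08	no_loss
syn_sp09	loss
syn_sp10	no_loss
syn_sp11	no_loss
syn_sp12	no_loss
syn_sp13	no_loss
syn_sp14	no_loss
syn_sp15	no_loss
syn_sp16	no_loss
syn_sp17	loss
syn_sp18	loss
syn_sp19	loss
syn_sp20	loss
syn_sp21	loss
syn_sp22	loss
syn_sp23	loss
syn_sp24	no_loss
syn_sp25	no_loss
syn_sp26	no_loss
syn_sp27	no_loss
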