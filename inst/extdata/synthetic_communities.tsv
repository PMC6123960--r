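location	species
loc01	syn_sp04
loc01	syn_sp17
loc01	syn_sp10
loc01	syn_sp09
loc02	syn_sp10
loc02	syn_sp09
loc02	syn_sp03
loc03	syn_sp05
loc03	syn_sp04
loc03	syn_sp27
loc04	syn_sp10
loc04	syn_sp02
loc04	syn_sp09
loc05	syn_sp05
loc05	syn_sp17
loc05	syn_sp09
loc06	syn_sp05
loc06	syn_sp10
loc06	syn_sp09
loc06	syn_sp02
loc06	syn_sp04
loc07	syn_sp04
loc07	syn_sp03
loc07	syn_sp17
loc08	syn_sp24
loc08	syn_sp09
loc08	syn_sp17
loc08	syn_sp04
loc08	syn_sp05
loc08	syn_sp10
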