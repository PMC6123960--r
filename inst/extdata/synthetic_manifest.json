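{
  "seed": 16,
  "n_tips": 27,
  "birth": 0.25,
  "death": 0.1,
  "q_iv": [0.123, 0.103, 0.052],
  "root_state": "D",
  "onto_rate": 0.03,
  "polymorphic": ["syn_sp03", "syn_sp05", "syn_sp24"],
  "unmeasured": ["syn_sp05", "syn_sp10", "syn_sp21", "syn_sp22", "syn_sp25"],
  "pool_species": ["syn_sp02", "syn_sp03", "syn_sp04", "syn_sp05", "syn_sp09", "syn_sp10", "syn_sp15", "syn_sp17", "syn_sp24", "syn_sp27"],
  "richness": [4, 3, 3, 3, 3, 5, 3, 6],
  "assembly": "dissimilar",
  "strength": 2
}
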