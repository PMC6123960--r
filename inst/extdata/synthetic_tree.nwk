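(((((syn_sp01:1.295381384,syn_sp02:1.295381384):1.295941108,((syn_sp03:0.9138113473,syn_sp04:0.9138113473):0.7389864245,(syn_sp05:0.03689422869,syn_sp06:0.03689422869):1.615903543):0.9385247197):2.483591873,(syn_sp07:4.533662646,syn_sp08:4.533662646):0.5412517189):6.266163092,(syn_sp09:5.168664624,((syn_sp10:2.939130756,(syn_sp11:1.940276977,(syn_sp12:0.4055055755,syn_sp13:0.4055055755):1.534771401):0.9988537798):0.8893190245,(syn_sp14:0.06872176988,syn_sp15:0.06872176988):3.759728011):1.340214843):6.172412833):4.270074394,(syn_sp16:7.184292011,((((((syn_sp17:1.920754422,syn_sp18:1.920754422):0.3744635334,syn_sp19:2.295217955):1.109536091,(syn_sp20:0.7572204986,syn_sp21:0.7572204986):2.647533547):0.1065357981,(syn_sp22:1.283935302,syn_sp23:1.283935302):2.227354542):2.15799062,(syn_sp24:3.768218479,(syn_sp25:0.05187394004,syn_sp26:0.05187394004):3.716344539):1.901061985):0.3451467261,syn_sp27:6.01442719):1.169864821):8.426859841);
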