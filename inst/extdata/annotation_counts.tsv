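species	n_annotated	n_total
B_terrestris	21638	27987
T_angustula	26623	33065
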