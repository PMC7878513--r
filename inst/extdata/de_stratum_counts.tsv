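species	n_nurse	n_forager
B_terrestris	436	767
T_angustula	179	62
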