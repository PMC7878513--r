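set	dataset	n_assigned	n_unassigned
B_terrestris_de	B_terrestris_trans	1162	176
T_angustula_de	T_angustula_trans	214	28
B_terrestris_transcriptome	B_terrestris_trans	29116	3312
T_angustula_transcriptome	T_angustula_trans	29408	7988
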