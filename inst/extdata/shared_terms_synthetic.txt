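basement membrane-specific heparan sulfate proteoglycan core protein
cytochrome c
histone h3
mucin-2-like
cytochrome p450
putative fatty acyl-coa reductase cg5065
cathepsin l
targeting protein for xklp2
venom acid phosphatase
glucose dehydrogenase
heat shock protein 83
alpha-amylase
elongation factor 1-alpha
arylphorin subunit alpha
chymotrypsin-1
piggybac transposable element-derived transposase
sugar transporter protein
cytochrome c oxidase subunit [fragment]
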