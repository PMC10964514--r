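pair_id	ligand_genes	receptor_genes
SPP1_CD44	SPP1	CD44
SPP1_ITGAV_ITGB1	SPP1	ITGAV;ITGB1
FGF1_FGFR1	FGF1	FGFR1
FGF2_FGFR1	FGF2	FGFR1
PDGFA_PDGFRA	PDGFA	PDGFRA
PTN_PTPRZ1	PTN	PTPRZ1
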