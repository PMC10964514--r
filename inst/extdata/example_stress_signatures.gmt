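hypoxia	illustrative hypoxia-response genes	VEGFA	HILPDA	CA9	PGK1	SLC2A1	NDRG1	ADM	BNIP3
glycolysis	illustrative glycolysis genes	PGK1	ENO1	LDHA	GAPDH	ALDOA	PKM	TPI1
oxidative_stress	illustrative oxidative-stress / ROS clearance genes	SOD1	SOD2	GPX1	GCLM	TXN	NQO1	HMOX1
reactive_gliosis	illustrative reactive astrocyte genes	GFAP	LGALS3	S100A10	SPP1	CD44	VIM
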