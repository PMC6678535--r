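cell_line	compound	condition	ic50_parental_uM	ic50_resistant_uM	ri_printed
HOS	MTX	drug_on	0.04	6.24	156
HOS	MTX	after_cdx	0.04	>100	>2000
HOS	DOXO	drug_on	0.06	11.3	212
HOS	DOXO	after_cdx	0.06	2.09	41.8
Saos-2-B	MTX	drug_on	0.05	1.93	37
Saos-2-B	MTX	after_cdx	0.05	2.05	34.2
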