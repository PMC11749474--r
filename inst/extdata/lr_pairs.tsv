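ligand	receptor	source
Bdnf	Ntrk2	neurotrophin
Mdk	Ptprz1	midkine
Ptn	Ptprz1	pleiotrophin
Dll1	Notch1	notch
Jag1	Notch1	notch
Igf1	Igf1r	growth_factor
Fgf2	Fgfr1	growth_factor
Fgf2	Fgfr3	growth_factor
Apoe	Lrp1	lipoprotein
Cxcl12	Cxcr4	chemokine
Shh	Ptch1	hedgehog
Vegfa	Flt1	angiogenic
Efnb2	Ephb4	ephrin
Egf	Egfr	growth_factor
Pdgfa	Pdgfra	growth_factor
Tgfb1	Tgfbr1	tgf_beta
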