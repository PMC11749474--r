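region: SVZ
NSC:
  positive: [Nr2e1, Thbs4, Igfbp5, Notum]
  negative: [Aqp4, Tril, Grin2c]
Astrocyte:
  positive: [Aqp4, Tril, Grin2c, Slc1a3]
  negative: [Thbs4, Notum]
TAP:
  positive: [Ascl1, Egfr, Hmgb2, Mki67]
  negative: []
NB:
  positive: [Dcx, Stmn2, Sox11]
  negative: []
OPC:
  positive: [Pdgfra, Cspg4, Olig1]
  negative: []
Oligodendrocyte:
  positive: [Plp1, Mbp, Mog]
  negative: []
Microglia:
  positive: [Cx3cr1, C1qa, Tmem119]
  negative: []
Endothelial:
  positive: [Cldn5, Pecam1, Flt1]
  negative: []
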