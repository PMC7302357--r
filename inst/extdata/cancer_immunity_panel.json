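{
  "steps": {
    "antigen_release": ["HMGB1", "CALR", "ANXA1", "HSP90AA1"],
    "antigen_presentation": ["HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2", "PSMB8", "PSMB9", "HLA-DRA", "HLA-DRB1"],
    "priming_activation": ["CD80", "CD86", "CD28", "CD40", "CD40LG", "IL2", "IL12A", "IL12B", "ICOS"],
    "trafficking": ["CXCL9", "CXCL10", "CXCL11", "CCL5", "CX3CL1"],
    "infiltration": ["ICAM1", "VCAM1", "SELE", "ITGAL", "ITGB2", "SELL"],
    "recognition": ["CD3D", "CD3E", "CD8A", "CD8B", "KLRK1", "TRAC"],
    "killing": ["GZMA", "GZMB", "PRF1", "IFNG", "FASLG", "GNLY"]
  },
  "checkpoint_genes": {
    "tolerance:CTLA4": ["CTLA4"],
    "tolerance:PD-1": ["PDCD1"],
    "tolerance:PD-L1/2": ["CD274", "PDCD1LG2"],
    "tolerance:TGF-beta": ["TGFB1"]
  },
  "decoy_genes": {
    "counterattack:DcR3": ["TNFRSF6B"],
    "counterattack:TRAILR4": ["TNFRSF10D"]
  },
  "effector_genes": ["GZMB", "PRF1", "IFNG"]
}
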