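{
  "gtp-hydrolysis": [
    {"chain": "A", "resnum": 251, "note": "alpha-Asp 251, catalytic"}
  ],
  "longitudinal-contact": [
    {"chain": "B", "resnum": 391, "note": "beta-Arg 391, inter-dimer contact"}
  ],
  "paclitaxel-site": [
    {"chain": "B", "resnum": 23,  "note": "beta-Val 23"},
    {"chain": "B", "resnum": 215, "note": "beta-Leu 215"},
    {"chain": "B", "resnum": 280, "note": "beta-Gln 280"},
    {"chain": "B", "resnum": 361, "note": "beta-Leu 361"}
  ],
  "colchicine-site": [
    {"chain": "B", "resnum": 239, "note": "beta-Cys 239"},
    {"chain": "A", "resnum": 180, "note": "alpha-Ala 180"},
    {"chain": "B", "resnum": 246, "note": "beta-Leu 246"}
  ],
  "vinca-site": [
    {"chain": "A", "resnum": 325, "note": "alpha-Pro 325"},
    {"chain": "B", "resnum": 177, "note": "beta-Asp 177"}
  ]
}
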