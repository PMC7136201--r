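# Central-carbon pathway definitions used by pathway_profiles().
# Each step is satisfied by any of its listed enzyme ids; the succinate
# dehydrogenase (SD) step accepts any subunit.
pathways:
  glycolysis:
    steps:
      - {id: HK,  enzymes: [HK]}
      - {id: PGI, enzymes: [PGI]}
      - {id: PFK, enzymes: [PFK]}
      - {id: ALD, enzymes: [ALD]}
      - {id: TPI, enzymes: [TPI]}
      - {id: G3P, enzymes: [G3P]}
      - {id: PGK, enzymes: [PGK]}
      - {id: PGM, enzymes: [PGM]}
      - {id: ENO, enzymes: [ENO]}
      - {id: PYK, enzymes: [PYK]}
  tca:
    steps:
      - {id: CS,   enzymes: [CS]}
      - {id: ACON, enzymes: [ACON]}
      - {id: ICD,  enzymes: [ICD]}
      - {id: aKDH, enzymes: [aKDH]}
      - {id: SCS,  enzymes: [SCS]}
      - {id: SD,   enzymes: [SD-A, SD-B, SD-C]}
      - {id: FH,   enzymes: [FH]}
      - {id: MDH,  enzymes: [MDH]}
  gluconeogenesis:
    steps:
      - {id: PEPCK, enzymes: [PEPCK]}
      - {id: FBP,   enzymes: [FBP]}
      - {id: G6P,   enzymes: [G6P]}
  glyoxylate:
    steps:
      - {id: ICL, enzymes: [ICL]}
      - {id: MS,  enzymes: [MS]}
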