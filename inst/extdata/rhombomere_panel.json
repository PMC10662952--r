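{
  "r1": ["irx1b"],
  "r2": ["vgll3", "tgfbr2b"],
  "r3": ["egr2b", "nab1b"],
  "r4": ["fgf3", "cyp26b1", "hoxb1a", "dusp2", "ppp1r14ab"],
  "r5": ["egr2b", "sema3ab", "mafba"],
  "r6": ["mafba", "crabp2a"]
}
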