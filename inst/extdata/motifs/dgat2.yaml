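# Hallmark screen for the DGAT2 (DAGAT) family.
# The conserved V-P-F-G block is the most diagnostic of the completely
# conserved residues; biochemically active homologs are known with an
# F->Y replacement, and individual gene models carry P->C and F->I/M
# variants, so those are tolerated (accepted but annotated) rather than
# disqualifying.
family: DGAT2
motifs:
  - name: conserved_block_VPFG
    positions: ["V", "P", "F", "G"]
    tolerated: ["", "C", "YIM", ""]
    required: true
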