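# Hallmark screen for soluble DGAT3-like acyltransferases.
# Most acyltransferase families require a catalytic histidine, usually
# accompanied by an aspartate or glutamate a few residues downstream
# (most frequently four); the spacer range 3-5 covers that spacing.
family: DGAT3
motifs:
  - name: acyltransferase_HxD
    positions: ["H", "DE"]
    spacers: [[3, 5]]
    required: true
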