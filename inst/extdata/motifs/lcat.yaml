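# Hallmark screen for the LCAT/PDAT superfamily.
# The structurally conserved salt bridge is an aspartate and an arginine
# separated by a single residue (Asp-X-Arg); the catalytic serine sits in
# a lipase-like G-x-S-x-G nucleophile elbow.
family: LCAT
motifs:
  - name: salt_bridge_DxR
    positions: ["D", "R"]
    spacers: [[1, 1]]
    required: true
  - name: nucleophile_elbow_GxSxG
    positions: ["G", "S", "G"]
    spacers: [[1, 1], [1, 1]]
    required: false
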