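# Default FOLH1 binding-pocket specification.
# 18 positions in four structural features; the five literature-named
# substrate-binding / arginine-patch positions are E424, R463, N519, R534,
# R536. The reference is a synthetic FOLH1 stand-in (see the FASTA header);
# swap in a curated FOLH1 sequence for production screening.
reference_fasta: folh1_synthetic.fasta
threshold: 60
features:
  zinc_binding:
    377: "H"
    387: "D"
    425: "E"
    453: "D"
    553: "H"
  substrate_binding:
    210: "R"
    257: "N"
    424: "E"
    518: "G"
    519: "N"
    699: "K"
    700: "Y"
  arginine_patch:
    463: "R"
    534: "R"
    536: "R"
  structural:
    541: "W"
    548: "G"
    552: "Y"
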