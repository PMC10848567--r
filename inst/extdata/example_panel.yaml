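# Example amplicon panel config (schema for load_panel()).
# Coordinates are 0-based, half-open, on the barcode frame.
# Primer sequences here are simulation placeholders; substitute the
# published cocktail sequences for real runs.
name: example_two_fragment
frame_length: 658
amplicons:
  - id: frag1
    start: 0
    end: 307
    fwd:
      name: frag1_F
      sequence: ACGGTCATGCAATTCGACTG
      anneal_start: 0
    rev:
      name: frag1_R
      sequence: TCAGGCTAACGTCATGGATC
      anneal_start: 306
  - id: frag2
    start: 251
    end: 658
    fwd:
      name: frag2_F
      sequence: TGCAACGTTAGCCATGACTC
      anneal_start: 251
    rev:
      name: frag2_R
      sequence: GTACCATCGGCTTGAACAGT
      anneal_start: 657
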