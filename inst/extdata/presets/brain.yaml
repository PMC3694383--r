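# Brain preset: operator parameter grid tuned for segmentation of
# transversal brain images (8-bit, 512x512). Values per parameter list the
# candidate set; the lead value is the default.
M:
  n1: [1, 2]
C:
  n2: [2, 3]
HG:
  n3: [2, 3]
  d: [1, 2, 3, 4]
CT:
  n4: [2, 3]
  n5: [1, 2]
  d: [1, 2, 3, 4]
ID:
  n6: [1, 2, 3]
  n7: [2]
  d: [1, 2, 3, 4]
ET:
  n8: [1, 2]
  n9: [1, 2]
  k1: [2]
  d: [1, 2, 3, 4]
CR:
  n10: [1, 2, 3]
  n11: [1, 3]
  d: [1, 3]
DE:
  n12: [2, 3, 4]
  n13: [2, 4]
  k2: [2]
  d: [2, 4]
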