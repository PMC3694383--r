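# Heart preset: operator parameter grid tuned for segmentation.
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
  n6: [2, 3]
  n7: [2]
  d: [2, 4]
ET:
  n8: [2, 3]
  n9: [2]
  k1: [2]
  d: [2, 4]
CR:
  n10: [1, 3]
  n11: [2, 3]
  d: [1, 2, 4]
DE:
  n12: [1, 4]
  n13: [2, 4]
  k2: [2]
  d: [1, 2, 4]
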