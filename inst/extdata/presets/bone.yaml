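# Bone preset: operator parameter grid tuned for segmentation. Bone imagery
# may also be scanned with overlapping windows (stride < window size).
M:
  n1: [1, 2]
C:
  n2: [2, 3, 4]
HG:
  n3: [2, 3, 4]
  d: [2, 4, 6]
CT:
  n4: [2, 3]
  n5: [2]
  d: [2, 3, 4]
ID:
  n6: [1, 3]
  n7: [2]
  d: [2, 3, 4]
ET:
  n8: [2, 3, 4]
  n9: [3]
  k1: [2]
  d: [2, 4]
CR:
  n10: [2, 4]
  n11: [2, 4, 6]
  d: [2, 4]
DE:
  n12: [3]
  n13: [3]
  k2: [2]
  d: [2, 4]
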