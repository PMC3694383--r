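# Liver preset: operator parameter grid tuned for segmentation.
# ID uses n7 = 3 (odd): the inverse-difference denominator then runs on
# |i - j|^n7, see ?inverse_difference.
M:
  n1: [1, 2]
C:
  n2: [2, 3]
HG:
  n3: [2, 3, 4]
  d: [1, 2, 3, 4]
CT:
  n4: [2, 3]
  n5: [1, 2]
  d: [1, 2, 3, 4]
ID:
  n6: [1, 3]
  n7: [3]
  d: [1, 2, 3, 4]
ET:
  n8: [1, 2, 3]
  n9: [3]
  k1: [2]
  d: [2, 3, 4]
CR:
  n10: [2, 4]
  n11: [3]
  d: [1, 2, 4, 6]
DE:
  n12: [1, 4]
  n13: [2]
  k2: [2]
  d: [1, 2, 3, 4]
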