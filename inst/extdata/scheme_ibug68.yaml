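# 68-point iBUG facial landmark scheme.
# Indices are 1-based: jaw 1-17, brows 18-27, nose 28-36, eyes 37-48,
# mouth 49-68 (outer 49-60, inner 61-68).
name: ibug68
size: 68
subsets:
  jaw: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17]
  left_brow: [18, 19, 20, 21, 22]
  right_brow: [23, 24, 25, 26, 27]
  nose: [28, 29, 30, 31, 32, 33, 34, 35, 36]
  left_eye: [37, 38, 39, 40, 41, 42]
  right_eye: [43, 44, 45, 46, 47, 48]
  mouth: [49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68]
  outer_mouth: [49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60]
  inner_mouth: [61, 62, 63, 64, 65, 66, 67, 68]
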