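# Default partition configuration for a 103-column Class I aaRS-like scaffold.
# Column intervals are 0-based, half-open [start, end).
# Segment layout: A (protozyme analog) 46 columns, B 17, C 20 (urzyme = 83),
# CP1 20 columns appended last. The composition values (A, B, C, CP1) are the
# segment-unit scores used as regression predictors; they are configuration
# values, not recomputed residue counts.
n_cols: 103
segments:
  A:   [[0, 46]]
  B:   [[46, 63]]
  C:   [[63, 83]]
  CP1: [[83, 103]]
masks:
  Full:
    intervals: [[0, 103]]
    composition: {A: 4, B: 3, C: 1, CP1: 2}
  urzyme:
    intervals: [[0, 83]]
    composition: {A: 4, B: 3, C: 1, CP1: 0}
  Protoz:
    intervals: [[0, 46]]
    composition: {A: 4, B: 0, C: 0, CP1: 0}
  CP1:
    intervals: [[83, 103]]
    composition: {A: 0, B: 0, C: 0, CP1: 2}
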