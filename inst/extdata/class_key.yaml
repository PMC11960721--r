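# Replaceable class -> physical-units key. Gaussian axes map each rank
# to [opt, var] in driver units (var in squared driver units); shading
# maps rank to canopy height (m), rooting to root-zone depth (m).
pH:
  1: [3.0, 0.8]
  2: [4.0, 0.8]
  3: [5.0, 0.8]
  4: [6.0, 0.8]
  5: [7.0, 0.8]
N:
  1: [0.0, 6.0]
  2: [2.5, 6.0]
  3: [5.0, 6.0]
  4: [7.5, 6.0]
  5: [10.0, 6.0]
moisture:
  1: [0.05, 0.08]
  2: [0.275, 0.08]
  3: [0.5, 0.08]
  4: [0.725, 0.08]
  5: [0.95, 0.08]
light:
  1: [0.02, 0.08]
  2: [0.265, 0.08]
  3: [0.51, 0.08]
  4: [0.755, 0.08]
  5: [1.0, 0.08]
shading:
  1: 0.05
  2: 0.2
  3: 0.5
  4: 1.0
  5: 1.8
rooting:
  1: 0.05
  2: 0.15
  3: 0.3
  4: 0.5
  5: 0.8
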