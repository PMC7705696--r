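# Material presets for neutron contrast calculations.
# Densities (g/cm^3) are documented literature approximations:
#   cellulose: crystalline cellulose I-beta; 3 hydroxyl H per anhydroglucose
#   lignin:    C9 phenylpropanoid monomer approximation, 1 phenolic OH
#   peg:       poly(ethylene glycol) repeat unit (end groups neglected)
#   d2o/h2o:   heavy / light water at ~22 C
cellulose:
  formula: {C: 6, H: 10, O: 5}
  density: 1.60
  n_exchangeable_H: 3
lignin:
  formula: {C: 9, H: 10, O: 3}
  density: 1.40
  n_exchangeable_H: 1
peg:
  formula: {C: 2, H: 4, O: 1}
  density: 1.125
  n_exchangeable_H: 0
d2o:
  formula: {D: 2, O: 1}
  density: 1.105
  n_exchangeable_H: 0
h2o:
  formula: {H: 2, O: 1}
  density: 0.997
  n_exchangeable_H: 2
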