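# Default six-state boundary configuration for the KOR intracellular
# conformational landscape.
#
# Axes: d   = distance Calpha(S153, 3.47) - Czeta(Y330, 7.53), Angstrom
#       chi = dihedral C-Ca-Cg-Cz of Y330 (7.53), degrees in (-180, 180]
# Intervals are half-open [lo, hi); a chi interval with lo > hi wraps
# across +/-180. Regions must be pairwise disjoint.
#
# The published state map shows the four base clusters only as heatmap
# density; these numeric intervals are a qualitative reading of that map
# and are the declared, hash-recorded configuration of every analysis run.
#
# Base states 2 and 3 split into A (R156 3.50 side chain facing
# intracellular) and B (not) substates; states 1 and 4 show essentially no
# downward R3.50 population and are not split.
split_by_r: [2, 3]
states:
  - base: 1          # canonical active: Y7.53 inward-packed, chi around -60
    d: [6.0, 11.0]
    chi: [-120.0, -20.0]
  - base: 2          # intermediate: chi flipped toward +60, TM7 still close
    d: [6.0, 11.0]
    chi: [20.0, 120.0]
  - base: 3          # alternative: Y7.53 dropped intracellularly, larger d
    d: [11.0, 17.0]
    chi: [20.0, 120.0]
  - base: 4          # Y7.53 toward TM1; seen only in simulation
    d: [11.0, 17.0]
    chi: [-160.0, -20.0]
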