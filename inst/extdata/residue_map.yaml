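# Ballesteros-Weinstein marker residues used for featurization, in author
# numbering of the human KOR constructs. chain may be null when the model
# has a single receptor chain.
S153:          # 3.47, TM3 reference Calpha
  chain: ~
  resno: 153
R156:          # 3.50, DRY arginine; orientation marker Ca -> Cz
  chain: ~
  resno: 156
Y330:          # 7.53, NPxxY tyrosine; dihedral C-Ca-Cg-Cz
  chain: ~
  resno: 330
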