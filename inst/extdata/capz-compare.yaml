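# Example run configuration for the cytoplasmic-CP vs CapZ comparison.
# Structure paths and chain letters must match your local copies of the
# deposited coordinate files (the heterodimer chain naming is not fixed by
# the depositions, so it is configured here rather than assumed).
#
# Residue ranges below are the published analysis selections:
#   - alpha subunit modeled 2-272 (of 281)
#   - beta subunit: exclude the flexible C-terminal tentacle (251-272)
#   - alpha 101-117: the flexibility/conformation contrast region
structures:
  a: 4AKR.pdb          # cytoplasmic CP (two heterodimer copies in the AU)
  b: 1IZN.pdb          # sarcomeric CapZ
pairings:
  - [A, A]             # alpha subunit vs alpha subunit
  - [B, B]             # beta subunit vs beta subunit
selections:
  alpha_modeled:
    a: {chain: A, include: [[2, 272]]}
    b: {chain: A, include: [[2, 272]]}
  beta_no_tentacle:
    a: {chain: B, include: [[1, 250]]}
    b: {chain: B, include: [[1, 250]]}
  alpha_101_117:
    a: {chain: A, include: [[101, 117]]}
    b: {chain: A, include: [[101, 117]]}
report:
  - alpha_101_117
  - beta_no_tentacle
b_mode: CA
disorder:
  - {structure: a, chain: B, expected: [1, 272]}
outdir: cp_compare_out
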