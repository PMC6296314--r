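# Example toxicity scenario: five doses, six-cycle window.
# Each dose carries a 3x3 per-cycle transition matrix over the maximal
# toxicity states {none, moderate, DLT}; rows are the current state.
# Under targets (p_mt, p_dlt) = (0.50, 0.25) the true MTD is dose 1 and
# both single-constraint MTDs coincide there.
name: coincide_mtd1
M: 6
doses:
  - - [0.891, 0.089, 0.020]
    - [0.000, 0.850, 0.150]
    - [0.000, 0.000, 1.000]
  - - [0.820, 0.130, 0.050]
    - [0.000, 0.750, 0.250]
    - [0.000, 0.000, 1.000]
  - - [0.740, 0.160, 0.100]
    - [0.000, 0.650, 0.350]
    - [0.000, 0.000, 1.000]
  - - [0.660, 0.180, 0.160]
    - [0.000, 0.550, 0.450]
    - [0.000, 0.000, 1.000]
  - - [0.570, 0.180, 0.250]
    - [0.000, 0.450, 0.550]
    - [0.000, 0.000, 1.000]
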