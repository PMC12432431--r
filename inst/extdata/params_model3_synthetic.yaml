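model: 3
provenance: synthetic defaults (not the published fitted tables)
residues:
- code: A
  mass: 71.078800000000001
  charge: 0.0
  sigma: 0.504
  eps: 0.34
  hydrophobic: yes
- code: R
  mass: 156.1875
  charge: 1.0
  sigma: 0.656
  eps: 0.45
  hydrophobic: no
- code: 'N'
  mass: 114.103800000000007
  charge: 0.0
  sigma: 0.568
  eps: 0.36
  hydrophobic: no
- code: D
  mass: 115.0886
  charge: -1.0
  sigma: 0.558
  eps: 0.25
  hydrophobic: no
- code: C
  mass: 103.138800000000003
  charge: 0.0
  sigma: 0.548
  eps: 0.44
  hydrophobic: no
- code: Q
  mass: 128.13069999999999
  charge: 0.0
  sigma: 0.602
  eps: 0.38
  hydrophobic: no
- code: E
  mass: 129.115499999999997
  charge: -1.0
  sigma: 0.592
  eps: 0.25
  hydrophobic: no
- code: G
  mass: 57.051900000000003
  charge: 0.0
  sigma: 0.45
  eps: 0.29
  hydrophobic: no
- code: H
  mass: 137.141099999999994
  charge: 0.375
  sigma: 0.608
  eps: 0.47
  hydrophobic: no
- code: I
  mass: 113.159400000000005
  charge: 0.0
  sigma: 0.618
  eps: 0.52
  hydrophobic: yes
- code: L
  mass: 113.159400000000005
  charge: 0.0
  sigma: 0.618
  eps: 0.52
  hydrophobic: yes
- code: K
  mass: 128.17410000000001
  charge: 1.0
  sigma: 0.636
  eps: 0.23
  hydrophobic: no
- code: M
  mass: 131.192599999999999
  charge: 0.0
  sigma: 0.618
  eps: 0.53
  hydrophobic: yes
- code: F
  mass: 147.176600000000008
  charge: 0.0
  sigma: 0.636
  eps: 0.74
  hydrophobic: no
- code: P
  mass: 97.116699999999994
  charge: 0.0
  sigma: 0.556
  eps: 0.41
  hydrophobic: no
- code: S
  mass: 87.078199999999995
  charge: 0.0
  sigma: 0.518
  eps: 0.3
  hydrophobic: no
- code: T
  mass: 101.105099999999993
  charge: 0.0
  sigma: 0.562
  eps: 0.32
  hydrophobic: no
- code: W
  mass: 186.213200000000001
  charge: 0.0
  sigma: 0.678
  eps: 0.87
  hydrophobic: no
- code: 'Y'
  mass: 163.175999999999988
  charge: 0.0
  sigma: 0.646
  eps: 0.71
  hydrophobic: no
- code: V
  mass: 99.132599999999996
  charge: 0.0
  sigma: 0.586
  eps: 0.46
  hydrophobic: yes
functionals:
- code: A
  a: -3.0e-06
  b: 0.0048
  c: 0.2
  alpha: 1.1
  Tref: 298.149999999999977
- code: V
  a: -3.0e-06
  b: 0.0056
  c: 0.2
  alpha: 1.1
  Tref: 298.149999999999977
- code: I
  a: -3.0e-06
  b: 0.0064
  c: 0.2
  alpha: 1.1
  Tref: 298.149999999999977
- code: L
  a: -3.0e-06
  b: 0.0064
  c: 0.2
  alpha: 1.1
  Tref: 298.149999999999977
- code: M
  a: -3.0e-06
  b: 0.006
  c: 0.2
  alpha: 1.1
  Tref: 298.149999999999977
bond:
  k: 1920.0
  r0: 0.381
wf:
  mu: 2.0
  nu: 1.0
solvent:
  d0: 165.199977719999993
  d1: -0.2920690248
  Trange:
  - 273.0
  - 373.0
electrolyte:
- z: 1.0
  c: 0.15
- z: -1.0
  c: 0.15
cutoffs:
  pairFactor: 3.0
  elec: 3.5
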