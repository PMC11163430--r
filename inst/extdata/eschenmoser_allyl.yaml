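ranks:
- level: 1
  label: semiempirical//hybrid-DFT
  u_G: 10.0
  u_barrier: 15.0
- level: 2
  label: DFT//hybrid-DFT
  u_G: 5.0
  u_barrier: ~
- level: 3
  label: DFT//local-CC
  u_G: ~
  u_barrier: pno
species:
- id: amide_acetal
  role: compound
  composition:
    C: 6
    H: 15
    'N': 1
    O: 2
  charge: 0
  c0: 1.0
  constituents: ~
  structures:
  - structure_id: amide_acetal_s1
    rank: 2
    components:
      E_elec: 0.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: allyl_alcohol
  role: compound
  composition:
    C: 3
    H: 6
    O: 1
  charge: 0
  c0: 1.0
  constituents: ~
  structures:
  - structure_id: allyl_alcohol_s1
    rank: 2
    components:
      E_elec: 0.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: methanol
  role: compound
  composition:
    C: 1
    H: 4
    O: 1
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: methanol_s1
    rank: 2
    components:
      E_elec: 0.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: methoxy_enamine
  role: compound
  composition:
    C: 5
    H: 11
    'N': 1
    O: 1
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: methoxy_enamine_s1
    rank: 2
    components:
      E_elec: 20.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: mixed_acetal
  role: compound
  composition:
    C: 8
    H: 17
    'N': 1
    O: 2
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: mixed_acetal_s1
    rank: 2
    components:
      E_elec: 15.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: ketene_aminal
  role: compound
  composition:
    C: 7
    H: 13
    'N': 1
    O: 1
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: ketene_aminal_s1
    rank: 2
    components:
      E_elec: 18.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: amide_product
  role: compound
  composition:
    C: 7
    H: 13
    'N': 1
    O: 1
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: amide_product_s1
    rank: 2
    components:
      E_elec: -122.700000000000003
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
reactions:
- id: elim1
  lhs:
    amide_acetal: 1
  rhs:
    methoxy_enamine: 1
    methanol: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: elim1_ts1
    rank: 3
    components:
      E_elec: 132.900000000000006
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: addition
  lhs:
    methoxy_enamine: 1
    allyl_alcohol: 1
  rhs:
    mixed_acetal: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: addition_ts1
    rank: 3
    components:
      E_elec: 100.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: elim2
  lhs:
    mixed_acetal: 1
  rhs:
    ketene_aminal: 1
    methanol: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: elim2_ts1
    rank: 3
    components:
      E_elec: 138.800000000000011
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: claisen
  lhs:
    ketene_aminal: 1
  rhs:
    amide_product: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: claisen_ts1
    rank: 3
    components:
      E_elec: 140.800000000000011
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0

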