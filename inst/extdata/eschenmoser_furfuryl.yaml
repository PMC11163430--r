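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
- id: furfuryl_alcohol
  role: compound
  composition:
    C: 5
    H: 6
    O: 2
  charge: 0
  c0: 1.0
  constituents: ~
  structures:
  - structure_id: furfuryl_alcohol_s1
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
  c0: 1.0
  constituents: ~
  structures:
  - structure_id: methoxy_enamine_s1
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
- id: mixed_acetal_f
  role: compound
  composition:
    C: 10
    H: 17
    'N': 1
    O: 3
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: mixed_acetal_f_s1
    rank: 2
    components:
      E_elec: 10.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: ketene_aminal_f
  role: compound
  composition:
    C: 9
    H: 13
    'N': 1
    O: 2
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: ketene_aminal_f_s1
    rank: 2
    components:
      E_elec: 5.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: post_claisen
  role: compound
  composition:
    C: 9
    H: 13
    'N': 1
    O: 2
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: post_claisen_s1
    rank: 2
    components:
      E_elec: -82.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: furan_amide
  role: compound
  composition:
    C: 9
    H: 13
    'N': 1
    O: 2
  charge: 0
  c0: 0.0
  constituents: ~
  structures:
  - structure_id: furan_amide_s1
    rank: 2
    components:
      E_elec: -170.400000000000006
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
reactions:
- id: addition_f
  lhs:
    furfuryl_alcohol: 1
    methoxy_enamine: 1
  rhs:
    mixed_acetal_f: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: addition_f_ts1
    rank: 3
    components:
      E_elec: 100.0
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: elim_f
  lhs:
    mixed_acetal_f: 1
  rhs:
    ketene_aminal_f: 1
    methanol: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: elim_f_ts1
    rank: 3
    components:
      E_elec: 147.099999999999994
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: claisen_f
  lhs:
    ketene_aminal_f: 1
  rhs:
    post_claisen: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: claisen_f_ts1
    rank: 3
    components:
      E_elec: 127.799999999999997
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0
- id: h_shift
  lhs:
    post_claisen: 1
  rhs:
    furan_amide: 1
  barrierless: no
  delta_pno: 0.0
  ts_structures:
  - structure_id: h_shift_ts1
    rank: 3
    components:
      E_elec: 101.700000000000003
      dG_vib: 0.0
      dG_rot: 0.0
      dG_trans: 0.0
      dG_solv: 0.0

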