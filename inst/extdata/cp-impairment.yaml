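name: cp-impairment
outcome: GMFM
latent:
- Injury
- MC
- Contracture
- Torsion
nodes: []
edges:
- Injury -> MC
- MC -> SCALE
- Age -> SCALE
- MC -> DMC
- Age -> DMC
- Injury -> Strength
- MC -> Strength
- Injury -> Spasticity
- Age -> Spasticity
- Strength -> AnkleDF
- Spasticity -> AnkleDF
- DMC -> AnkleDF
- SCALE -> AnkleDF
- Age -> AnkleDF
- Contracture -> AnkleDF
- Strength -> KneeExt
- Spasticity -> KneeExt
- DMC -> KneeExt
- SCALE -> KneeExt
- Age -> KneeExt
- Contracture -> KneeExt
- Strength -> Popliteal
- Spasticity -> Popliteal
- DMC -> Popliteal
- SCALE -> Popliteal
- Age -> Popliteal
- Contracture -> Popliteal
- Strength -> HipExt
- Spasticity -> HipExt
- DMC -> HipExt
- SCALE -> HipExt
- Age -> HipExt
- Contracture -> HipExt
- Strength -> TibRot
- Spasticity -> TibRot
- DMC -> TibRot
- SCALE -> TibRot
- Age -> TibRot
- Torsion -> TibRot
- Strength -> FemRot
- Spasticity -> FemRot
- DMC -> FemRot
- SCALE -> FemRot
- Age -> FemRot
- Torsion -> FemRot
- Strength -> GDI
- Spasticity -> GDI
- DMC -> GDI
- SCALE -> GDI
- Age -> GDI
- AnkleDF -> GDI
- KneeExt -> GDI
- Popliteal -> GDI
- HipExt -> GDI
- TibRot -> GDI
- FemRot -> GDI
- Strength -> GMFM
- Spasticity -> GMFM
- DMC -> GMFM
- SCALE -> GMFM
- Age -> GMFM
- AnkleDF -> GMFM
- KneeExt -> GMFM
- Popliteal -> GMFM
- HipExt -> GMFM
- GDI -> GMFM
variables:
- name: Age
  role: age
  units: years
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 0.0
  - 21.0
- name: SCALE
  role: exposure
  units: scale points
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 0.0
  - 10.0
- name: DMC
  role: exposure
  units: index points
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 22.0
  - .inf
- name: Strength
  role: exposure
  units: scale points
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 0.0
  - 5.0
- name: Spasticity
  role: exposure
  units: scale points
  sign_flip: yes
  predictive_flip: no
  td_offset: 0.0
  range:
  - 0.0
  - 5.0
- name: AnkleDF
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 21.30000000000000071
  range:
  - -90.0
  - 30.0
- name: KneeExt
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 4.0
  range:
  - -90.0
  - 30.0
- name: Popliteal
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 25.60000000000000142
  range:
  - -120.0
  - 40.0
- name: HipExt
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 0.0
  range:
  - -60.0
  - 30.0
- name: TibRot
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 16.0
  range:
  - -60.0
  - 60.0
- name: FemRot
  role: exposure
  units: deg
  sign_flip: no
  predictive_flip: yes
  td_offset: 26.89999999999999858
  range:
  - -60.0
  - 60.0
- name: GDI
  role: exposure
  units: index points
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 20.0
  - 130.0
- name: GMFM
  role: outcome
  units: GMFM-66 points
  sign_flip: no
  predictive_flip: no
  td_offset: 0.0
  range:
  - 0.0
  - 100.0
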