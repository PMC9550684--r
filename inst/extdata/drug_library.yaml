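# Drug parameter library.
# Provenance: literature-order defaults assembled for the desk-scale
# simulator (NOT fitted to any specific trial or cohort); every value is
# overridable via a user-supplied library file.
# Units: k_el, k12, k21, kill_max in 1/h; V_d in L; IC50 in mg/L;
# dose in mg (already body-surface-area resolved).
drugs:
  - name: doxorubicin
    k_el: 0.029          # effective half-life ~24 h (lumped 1-compartment)
    V_d: 700
    kill_max: 0.0040
    IC50: 0.05
    hill: 1.0
    relative_permeability: 1.0
  - name: cyclophosphamide
    k_el: 0.10           # half-life ~7 h
    V_d: 40
    kill_max: 0.0030
    IC50: 3.0
    hill: 1.0
    relative_permeability: 1.0
  - name: paclitaxel
    k_el: 0.035          # half-life ~20 h
    V_d: 250
    kill_max: 0.0030
    IC50: 0.02
    hill: 1.0
    relative_permeability: 1.0
  - name: docetaxel
    k_el: 0.060
    V_d: 110
    kill_max: 0.0035
    IC50: 0.02
    hill: 1.0
    relative_permeability: 1.0
  - name: carboplatin
    k_el: 0.23           # half-life ~3 h
    V_d: 17
    kill_max: 0.0025
    IC50: 2.0
    hill: 1.0
    relative_permeability: 1.0
  - name: trastuzumab
    k_el: 0.0010         # half-life ~28 d
    V_d: 3.0
    kill_max: 0.0020
    IC50: 10.0
    hill: 1.0
    relative_permeability: 0.1   # antibody: slow extravasation
    growth_multiplier: 0.5
  - name: pertuzumab
    k_el: 0.0016         # half-life ~18 d
    V_d: 3.1
    kill_max: 0.0015
    IC50: 20.0
    hill: 1.0
    relative_permeability: 0.1
    growth_multiplier: 0.7
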