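# Population parameter defaults for the linearized glucose-insulin model.
# Values are representative adult-T1D magnitudes assembled from the minimal-
# model and long-acting-insulin absorption literature; each section records
# its provenance. Units are stated per key. Internal conventions: insulin
# amounts in U, carbohydrate masses in mg, glucose in mg/dL, time in minutes.
population:
  source: >-
    Subcutaneous oral glucose minimal model literature (adult T1D population
    magnitudes); Si expressed in mL/U/min so that Si*Gb*x2 is mg/dL/min with
    plasma insulin carried in U and distributed over Vi*BW mL.
  Sg: 0.010     # glucose effectiveness, 1/min
  Gb: 115       # basal (target fasting) glucose, mg/dL
  Vg: 1.6       # glucose distribution volume, dL/kg
  BW: 70        # body weight, kg
  p2: 0.012     # insulin action rate, 1/min
  Vi: 120       # insulin distribution volume, mL/kg
  Si: 700       # insulin sensitivity, mL/U/min
  kc1: 0.0025   # rapid insulin: direct sc -> plasma, 1/min
  kc12: 0.017   # rapid insulin: sc1 -> sc2 transfer, 1/min
  kc2: 0.017    # rapid insulin: sc2 -> plasma, 1/min
  kcl: 0.10     # plasma insulin clearance, 1/min
basal_pk:
  source: >-
    Long-acting (glargine-type) subcutaneous absorption: near-complete
    precipitation at the injection site with day-scale redissolution,
    giving the peak-less 24 h profile the formulation is designed for.
  F: 0.75         # bioavailability, dimensionless
  precip_fraction: 0.98  # fraction of the dose precipitating on injection
  ksp: 0.00025    # precipitate -> soluble dissolution rate, 1/min
  ka: 0.00040     # soluble depot -> plasma absorption rate, 1/min
meal:
  source: >-
    Two-compartment oral carbohydrate absorption (stomach/gut) with a small
    direct-absorption path; rates give a ~70 min appearance peak.
  f: 0.90        # carbohydrate bioavailability, dimensionless
  kq1: 0.002     # direct stomach absorption, 1/min
  kq12: 0.015    # stomach -> gut transfer, 1/min
  kq2: 0.012     # gut absorption, 1/min
rescue:
  source: >-
    Fast-acting rescue carbohydrates (glucose tablets): near-complete and
    rapid absorption, appearance peak ~20 min.
  f: 1.0
  kq1: 0.005
  kq12: 0.09
  kq2: 0.09
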