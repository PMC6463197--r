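# Method definition: 14 halogenated target analytes + 2 internal standards
# monitored by GC-QqQ-MS/MS in MRM mode. Transitions are metadata only.
# cert_expanded_u_pct is the expanded relative uncertainty of the standard
# purity from the supplier certificate (coverage factor 2); where a compound
# carries no certificate (hexachloro-1,3-butadiene, lindane) the purity
# drives a rectangular-distribution estimate instead. Certificate values are
# reconstructed from the published uncertainty budget of the validation
# study; purities for the certificate-bearing standards are representative
# values within the supplier-stated ranges (98.1-99.5% for the Dr.
# Ehrenstorfer organochlorines, >= 98% for the CIL PBDE solutions).
analytes:
  - name: Hexachloro-1,3-butadiene
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 4.42
    quant_transition: "225>190 @15V"
    qual_transition: "260>225 @15V"
    purity_pct: 96.0
  - name: Pentachlorobenzene
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 6.12
    quant_transition: "248>213 @25V"
    qual_transition: "250>180 @20V"
    purity_pct: 99.0
    cert_expanded_u_pct: 0.50
  - name: Tetrachloro-m-xylene
    role: internal_standard
    is_ref: ""
    rt_min: 6.79
    quant_transition: "244>209 @15V"
    qual_transition: "171>136 @15V"
    purity_pct: 99.0
    is_conc: 10
  - name: alpha-HCH
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 7.36
    quant_transition: "219>183 @5V"
    qual_transition: "217>181 @15V"
    purity_pct: 98.5
    cert_expanded_u_pct: 0.95
  - name: Hexachlorobenzene
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 7.50
    quant_transition: "284>214 @35V"
    qual_transition: "284>249 @20V"
    purity_pct: 99.5
    cert_expanded_u_pct: 2.00
  - name: beta-HCH
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 7.75
    quant_transition: "219>183 @5V"
    qual_transition: "217>181 @15V"
    purity_pct: 98.1
    cert_expanded_u_pct: 0.30
  - name: Lindane
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 7.86
    quant_transition: "219>183 @5V"
    qual_transition: "217>181 @15V"
    purity_pct: 97.0
  - name: delta-HCH
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 8.22
    quant_transition: "219>183 @5V"
    qual_transition: "217>181 @15V"
    purity_pct: 98.4
    cert_expanded_u_pct: 0.66
  - name: Heptachlor
    role: analyte
    is_ref: Tetrachloro-m-xylene
    rt_min: 9.02
    quant_transition: "272>237 @25V"
    qual_transition: "272>117 @35V"
    purity_pct: 99.1
    cert_expanded_u_pct: 0.50
  - name: BDE-28
    role: analyte
    is_ref: BDE-77
    rt_min: 11.94
    quant_transition: "246>139 @30V"
    qual_transition: "406>246 @20V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.59
  - name: BDE-47
    role: analyte
    is_ref: BDE-77
    rt_min: 14.02
    quant_transition: "326>217 @30V"
    qual_transition: "486>326 @20V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.60
  - name: BDE-77
    role: internal_standard
    is_ref: ""
    rt_min: 14.74
    quant_transition: "326>217 @30V"
    qual_transition: "486>326 @20V"
    purity_pct: 98.0
    is_conc: 20
  - name: BDE-100
    role: analyte
    is_ref: BDE-77
    rt_min: 15.55
    quant_transition: "564>404 @20V"
    qual_transition: "404>297 @30V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.60
  - name: BDE-99
    role: analyte
    is_ref: BDE-77
    rt_min: 15.97
    quant_transition: "564>404 @20V"
    qual_transition: "404>297 @30V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.60
  - name: BDE-154
    role: analyte
    is_ref: BDE-77
    rt_min: 17.19
    quant_transition: "644>484 @20V"
    qual_transition: "484>324 @40V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.60
  - name: BDE-153
    role: analyte
    is_ref: BDE-77
    rt_min: 17.84
    quant_transition: "644>484 @20V"
    qual_transition: "484>324 @40V"
    purity_pct: 98.0
    cert_expanded_u_pct: 0.60

# NIST SRM 1946 (Lake Superior fish tissue): certified concentrations with
# expanded uncertainties, ug/kg wet weight.
srm_certified:
  - {analyte: Hexachlorobenzene, certified_conc: 7.25, certified_expanded_u: 0.83}
  - {analyte: alpha-HCH,         certified_conc: 5.72, certified_expanded_u: 0.65}
  - {analyte: Lindane,           certified_conc: 1.14, certified_expanded_u: 0.18}
  - {analyte: BDE-28,            certified_conc: 0.742, certified_expanded_u: 0.027}
  - {analyte: BDE-47,            certified_conc: 29.9, certified_expanded_u: 2.3}
  - {analyte: BDE-99,            certified_conc: 18.5, certified_expanded_u: 2.1}
  - {analyte: BDE-100,           certified_conc: 8.57, certified_expanded_u: 0.52}
  - {analyte: BDE-153,           certified_conc: 2.81, certified_expanded_u: 0.41}
  - {analyte: BDE-154,           certified_conc: 5.77, certified_expanded_u: 0.80}

# Analytical Eco-Scale penalty ledger for the whole procedure (per-sample
# reagent amounts in the notes).
ecoscale:
  - {category: reagent, label: MeCN, amount_note: 5 mL, penalty_points: 4}
  - {category: reagent, label: CHCl3, amount_note: 50 uL, penalty_points: 2}
  - {category: reagent, label: Hexane, amount_note: 80 uL, penalty_points: 8}
  - {category: reagent, label: Analytes standard solution, amount_note: "", penalty_points: 4}
  - {category: reagent, label: H2O, amount_note: 4 mL, penalty_points: 0}
  - {category: reagent, label: H2SO4, amount_note: 1 mL, penalty_points: 2}
  - {category: reagent, label: MgSO4, amount_note: 2 g, penalty_points: 0}
  - {category: reagent, label: NaCl, amount_note: 0.5 g, penalty_points: 0}
  - {category: reagent, label: CH3COONa, amount_note: "", penalty_points: 0}
  - {category: instrument, label: Vortex, amount_note: "", penalty_points: 1}
  - {category: instrument, label: Centrifuge, amount_note: "", penalty_points: 1}
  - {category: instrument, label: GC-MS/MS, amount_note: "", penalty_points: 3}
  - {category: occupational_hazard, label: Occupational hazard, amount_note: "", penalty_points: 3}
  - {category: waste, label: Waste, amount_note: "", penalty_points: 4}
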