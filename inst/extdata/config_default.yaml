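# Default pipeline configuration. Any subset may be overridden; values
# absent here fall back to the package defaults (see ?default_config).
io:
  aliases:
    hb: [hb, hemoglobin, hb_gdl]
    ferritin: [ferritin, sf, ferritin_ngml]
    vita: [vita, rbp, retinol, vitamin_a]
adjustment:
  enabled: true
  altitude_coeff_linear: -0.032   # g/dL per thousand feet
  altitude_coeff_quad: 0.022      # g/dL per thousand feet squared
  altitude_floor: 1000            # m; below this no adjustment is needed
  smoking_decrement: 0.3          # g/dL, women who smoke
  altitude_unit_factor: 0.0032808 # thousand feet per meter
healthy:
  ferritin_min_child: 12   # ng/mL
  ferritin_min_woman: 15   # ng/mL
  vita_min: 20.1           # ug/dL (RBP or retinol), where measured
  crp_max: 0.5             # mg/dL, where measured
  agp_max: 1               # g/L, where measured
  require_no_malaria: true
  min_healthy_per_survey: 100
quantile:
  p: 0.05
  level: 0.95
meta:
  level: 0.95
  tol: 1.0e-8
  max_iter: 200
lqmm:
  p: 0.05
  method: exact   # or gh (plain Gauss-Hermite)
  nodes: 11       # used by method gh
  restarts: 3
  covariates: [age, age2, sex]
  age_unit: years
spline:
  B: 5000
  level: 0.95
synthetic:
  group: child
  seed: 20260929
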