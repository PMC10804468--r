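- structure: body
  metric: Dmax
  limit: 115.0
  limit_unit: pct_rx
  dose_gy: .na.real
- structure: brainstem
  metric: Dmax
  limit: 54.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: cochlea
  metric: Dmean
  limit: 40.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: constrictors
  metric: Dmean
  limit: 50.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: larynx
  metric: Dmean
  limit: 50.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: mandible
  metric: Dmax
  limit: 75.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: oral_cavity
  metric: Dmean
  limit: 50.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: spinal_cord
  metric: Dmax
  limit: 48.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: parotid
  metric: Dmean
  limit: 26.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: parotid
  metric: V20Gy
  limit: 50.0
  limit_unit: pct_vol
  dose_gy: 20.0
- structure: esophagus
  metric: Dmean
  limit: 40.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: eye
  metric: Dmax
  limit: 45.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: optic_nerve
  metric: Dmax
  limit: 50.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: optic_chiasm
  metric: Dmax
  limit: 50.0
  limit_unit: Gy
  dose_gy: .na.real
- structure: submandibular
  metric: Dmean
  limit: 39.0
  limit_unit: Gy
  dose_gy: .na.real
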