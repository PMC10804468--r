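larynx_edema:
  endpoint: larynx_edema_grade2plus
  structure: larynx
  'n': 0.45
  m: 0.18
  td50: 46.3
  source: LKB fit family for grade >= 2 larynx edema (synthetic stand-in)
dysphagia:
  endpoint: dysphagia_grade2plus
  structure: constrictors
  'n': 1.0
  m: 0.25
  td50: 50.0
  source: mean-dose LKB stand-in for grade >= 2 dysphagia
xerostomia:
  endpoint: xerostomia
  structure: parotid_ips
  'n': 1.0
  m: 0.4
  td50: 39.9
  source: mean-dose LKB stand-in for parotid xerostomia
esophagitis:
  endpoint: acute_esophagitis_grade2plus
  structure: esophagus
  'n': 0.69
  m: 0.36
  td50: 47.0
  source: LKB stand-in for grade >= 2 acute esophagitis
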