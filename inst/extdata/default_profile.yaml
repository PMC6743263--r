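org_root: 1.2.410.200001
default_private_action: E
date_blank: no
scan_keywords:
- name
- birth
- patient
- hosp
- phone
- tel
- addr
- physician
- id
- amc
- severance hospital
- samsung medical center
- snu hospital
- st elsewhere general
number_patterns:
  phone: \d{3}-\d{4}-\d{4}
  national_id: (?<!\d)\d{6,7}(?!\d)
  date_like: (?<!\d)(19|20)\d{6}(?!\d)
rules:
- tag: (0010,0010)
  action: 'N'
  n_source: initial
- tag: (0002,0003)
  action: C
- tag: (0008,0018)
  action: C
- tag: (0008,0050)
  action: E
- tag: (0008,0080)
  action: D
- tag: (0008,0081)
  action: E
- tag: (0008,0090)
  action: E
- tag: (0008,1050)
  action: E
- tag: (0010,0020)
  action: 'N'
  n_source: subject_no
- tag: (0010,0030)
  action: R
- tag: (0010,1001)
  action: E
- tag: (0010,1002)
  action: E
- tag: (0010,1040)
  action: E
- tag: (0020,0010)
  action: 'N'
  n_source: project_id
- tag: (0020,000D)
  action: C
- tag: (0020,000E)
  action: C
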