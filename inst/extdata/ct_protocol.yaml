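modality: CT
required_orientations: ~
rules:
- parameter: rows
  comparator: eq
  threshold: 512.0
  units: .na.character
  optional: no
  tolerance: 1.0e-06
- parameter: columns
  comparator: eq
  threshold: 512.0
  units: .na.character
  optional: no
  tolerance: 1.0e-06
- parameter: slice_thickness
  comparator: le
  threshold: 5.0
  units: mm
  optional: no
  tolerance: 1.0e-06
- parameter: interslice_gap
  comparator: eq
  threshold: 0.0
  units: mm
  optional: no
  tolerance: 0.001
- parameter: modality
  comparator: in_set
  threshold: CT
  units: .na.character
  optional: no
  tolerance: 1.0e-06
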