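Package: ctimr
Title: Clinical Trial Imaging Management: DICOM Deidentification, Quality
    Control, Part-11 Records and Imaging eCRF Export
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing medical imaging data in multicenter clinical
    trials: rule-driven DICOM deidentification with action codes, study-wide
    consistent UID remapping and burned-in text blackout; automatic
    protocol-conformance image quality control with quality assessment
    reports; 21 CFR Part 11 style record keeping (hash-chained audit trails,
    electronic signatures, CAPA query lifecycle, role-based blinding); and an
    imaging case report form layer with RECIST 1.1 response derivation and
    CDISC SDTM-style tabulation export. Includes a synthetic DICOM study
    generator with a ground-truth PHI manifest for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
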