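Package: potdassess
Title: Quantitative Plan-of-the-Day Assessment for Library-Based Adaptive
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative plan-of-the-day (POTD) selection in
    CBCT-guided adaptive radiotherapy of cervical cancer. Provides a binary
    mask volume data model with NIfTI input/output and physical-unit
    morphology (uniform and directional margin expansion), target and
    organ-at-risk coverage metrics, mask-to-mask deformable registration
    (affine initialisation plus fast symmetric-forces demons) for
    propagating the high-risk CTV onto daily anatomy, a configurable
    quantitative standard operating procedure (qSOP) that classifies
    library plans as optimal, acceptable or unacceptable, a synthetic
    female-pelvis phantom and plan-library builder for end-to-end testing,
    and plan-assessment reports in text, JSON and CSV form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
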