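Package: ricotem
Title: Ristocetin-Modified Thromboelastometry Screening for von Willebrand Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for a ristocetin-modified rotational
    thromboelastometry (ROTEM) screening assay for von Willebrand disease
    (VWD). Extracts standard viscoelastic parameters (CT, CFT, MCF) and the
    30-minute area under the clot-velocity curve from amplitude traces,
    computes the Ricotem- and Ricotem+ ratio statistics from the Extem,
    ristocetin and ristocetin-plus-VWF-concentrate assay channels, assigns
    responder groups at configurable cut-offs, classifies laboratory VWD
    phenotypes from conventional hemostasis panels, and evaluates screening
    cut-off performance. Includes a mechanistic simulator of whole-blood
    clot-formation curves under the three assay conditions so the whole
    pipeline is testable without patient data, plus an advisory extension of
    a ROTEM-based bleeding-management algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
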