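Package: cowcvr
Title: Territorial Cerebrovascular Resistance from Circle of Willis Flow Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subject-specific estimation of territorial cerebrovascular
    resistance (CVR) of the middle, anterior and posterior cerebral artery
    territories. Per-artery mean flow rates (as obtained from 4D flow MRI)
    and systemic pressure are combined with a reduced-order steady laminar
    flow model of the circle of Willis: the network is split into anterior
    and posterior domains, boundary conditions are assembled from the
    measured flows with signed handling of the posterior communicating
    arteries, nodal analysis yields perfusion pressures at cut planes 5 mm
    from the bifurcations, and territorial and total CVR follow from an
    Ohm's-law relation against intracranial pressure. A forward simulator
    with known ground-truth resistances, a synthetic cohort generator, and
    cohort statistics (group comparisons, a conductance-volume linear mixed
    model, Bonferroni thresholding and ICC(2,1)) make the inverse pipeline
    testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    graphics,
    lme4,
    lmerTest,
    nortest,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
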