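Package: momaknock
Title: Bi-Level Strain Design with Minimization of Metabolic Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies reaction knockouts in constraint-based metabolic
    network models that maximize the production flux of a target chemical
    while the mutant phenotype is predicted by minimization of metabolic
    adjustment (MOMA). The bi-level program (outer: choose up to K
    knockouts; inner: quadratic MOMA flux response) is solved exactly by
    adaptive piecewise linearization of the inner objective and an LP
    strong-duality reduction to a single-level mixed-integer linear
    program. Includes flux balance analysis, MOMA evaluation of arbitrary
    knockout sets, an OptKnock-style biomass-maximization baseline, a
    brute-force enumeration oracle, a synthetic network generator, and
    readers for SBML Level 3 (fbc) and a plain-text model dialect.
License: MIT
Encoding: UTF-8
Imports:
    quadprog,
    jsonlite,
    xml2,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
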