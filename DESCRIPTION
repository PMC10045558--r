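Package: borondose
Title: Mixed-Field Dosimetry, Radiobiology and Survival Analysis for
    Boron Neutron Capture Therapy Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for preclinical boron neutron capture therapy
    (BNCT) studies: decomposition of the mixed neutron/photon field into the
    boron-capture, nitrogen-capture, proton-recoil and gamma physical dose
    components and their CBE/RBE-weighted photon-equivalent dose; estimation
    of clonogenic survival fractions and linear-quadratic (LQ) model fitting
    with endpoint-dose inversion and beam RBE / compound biological
    effectiveness (CBE) derivation; summarisation of tissue and cellular
    boron biodistribution (tumor-to-brain and tumor-to-blood ratios, washout
    retention); Kaplan-Meier, log-rank and percent increase-in-life-span
    statistics for grouped animal survival data; and calibrated synthetic
    generators for every input table so the whole pipeline is testable
    without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
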