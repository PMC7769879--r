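Package: electroferm
Title: Carbon and Electron Balance Accounting for Lactate Electrofermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing batch electrofermentation experiments in
    two-chamber bioelectrochemical cells fed with lactate: a degree-of-reduction
    compound registry, carbon and electron (charge) balance ledgers,
    electrofermentation performance coefficients, specific energy consumption,
    interval production rates and per-cycle molar yields, stoichiometric
    decomposition of concentration changes into metabolic reaction extents
    (lactate fermentation, homoacetogenesis, chain elongation, hydrogen
    evolution) with CO2-recycling quantification, and cyclic-voltammetry
    first-derivative peak analysis. A seeded simulator generates complete
    synthetic cell experiments and voltammograms with known ground truth so
    every stage of the pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
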