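Package: SpectraScreen
Title: Non-Targeted Tandem Mass Spectral Library Search for Drug Screening
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for qualitative drug screening by non-targeted
    LC-MS/MS with data-dependent acquisition (DDA). Provides centroided
    tandem mass spectrum containers and I/O (MGF, MSP-like libraries, a
    simplified centroided mzML dialect), curation and modelling of
    multi-collision-energy reference libraries, a library-search engine
    producing compound-level average match probability (amp) and relative
    average match probability (ramp) scores with fixed identification
    thresholds, a validation layer (selectivity/specificity, sensitivity,
    limits of identification from dilution series, logP applicability
    window, two-method agreement), and a synthetic-data module that
    simulates QqTOF breakdown curves, oral-fluid matrix background and the
    DDA duty cycle (top-N selection, intensity trigger, dynamic exclusion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectrum-utils.R'
    'spectra-io.R'
    'library.R'
    'search.R'
    'validation.R'
    'synthetic.R'
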