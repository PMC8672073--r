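Package: lightpotential
Title: Light Potentials of Photosynthesis from Field Phenotyping Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rapid light-response ("light potential")
    measurements of photosynthesis collected in the field with pulse-modulated
    fluorescence and absorbance spectroscopy. Derives photosynthetic parameters
    (PSII quantum efficiency, linear electron flow, total non-photochemical
    quenching, QA redox state, thylakoid proton motive force via the
    electrochromic shift, ATP synthase proton conductivity, P700 oxidation)
    from raw three-phase protocol signals, applies declarative quality-control
    flagging, clusters responses against environmental covariates with a
    Gaussian mixture model fitted by expectation-maximization with BIC model
    selection, and classifies mechanistic limitations to light use (PSI
    acceptor-side limitation, rapid NPQ, photosynthetic control) from the sign
    structure of light-induced changes. A ground-truthed synthetic-leaf
    simulator supports end-to-end validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    minpack.lm,
    mclust,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
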