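Package: agshydro
Title: Hydrolytic Enzyme Activity and Anaerobic Feeding Capacity of Aerobic
    Granular Sludge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes chromogenic enzyme-assay time series (p-nitrophenyl and
    azocasein substrates) into quality-controlled hydrolytic activities of
    aerobic granular sludge fractions, converts dye-release rates to substrate
    and COD hydrolysis rates, aggregates activities to reactor level, and
    estimates the maximum hydrolyzable substrate per litre of influent during
    anaerobic plug-flow feeding with a tanks-in-series bed model. Includes a
    synthetic assay-campaign generator with known ground truth, influent
    characterization utilities, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
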