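Package: raynaudbd
Title: Objective Quantification of Raynaud's Phenomenon Attacks from
    Smartphone Hand Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the skin colour change of Raynaud's phenomenon
    attacks from smartphone photographs of the hands. Defines 25 regions of
    interest (24 on the digits, one dorsal reference), converts region
    pixels to CIE L*a*b* colour space, and scores each digit region's
    colour shift against the within-image dorsal reference with the
    Bhattacharyya distance. Images are grouped into attack episodes from
    their EXIF timestamps, per-attack mean distances are joined to
    patient-reported severity, and the association is tested with Pearson
    correlation, two-factor ANOVA (patient and severity) and Tukey
    honestly-significant-difference comparisons. Includes a synthetic
    fixture generator that renders stylised hand images with known colour
    shifts and ground-truth masks so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
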