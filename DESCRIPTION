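Package: kmdlign
Title: Kendrick Mass Defect Analysis and CHNOS Formula Assignment for
    Lignin ESI-HRMS Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing complex
    lignin mixtures from centroided high-resolution electrospray mass
    spectra. Reads two-column ASCII peak lists with sample and solvent
    metadata, performs blank subtraction, noise and relative-intensity
    filtering, transforms spectra into Kendrick mass-defect space with an
    arbitrary repeating-unit base, gates peak groups with reproducible
    polygon files, assigns CHNOS molecular formulas by exact-mass
    decomposition within a ppm window with double-bond-equivalent and
    valence filters, summarizes gated groups by KM/KMD, H/C, O/C, DBE and
    heteroatom class, ranks extraction solvents by recovered peak counts,
    and ships a synthetic lignin-spectrum generator with full ground
    truth for end-to-end benchmarking.
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
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
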