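Package: urchingo
Title: Reproductive Potential of Sea Urchin Populations from Gonadosomatic
    Index Time Series and Quadrat Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the potential reproductive contribution of sea urchin
    (Paracentrotus lividus) populations from monthly morphometric samples and
    quadrat census counts. Computes per-individual gonadosomatic index (GSI),
    aggregates monthly per-size-class GSI series, detects spawning events as
    peak-to-trough declines of mean GSI, and cascades the per-event individual
    gamete output through size-class densities to population-level totals
    (GO, TGO, MGO, popTGO, popMGO). Includes Cochran's C homogeneity statistic
    and a synthetic-data generator that emulates annual GSI cycles, Poisson
    quadrat counts and binomial fertility assays, so the whole pipeline can be
    exercised and its parameter recovery demonstrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
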