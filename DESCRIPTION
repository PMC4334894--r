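Package: nilhi
Title: Genome-Wide Hybrid-Incompatibility Mapping with Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping hybrid-incompatibility (HI) loci between
    closely related nematode species using marker-assisted introgression
    (near-isogenic) lines. Provides interval algebra and genome-coverage
    landscape statistics on cb4-sized chromosomes, introgression boundary
    calling from ordered species-specific PCR marker calls with
    assembly-error flagging, read-depth window based boundary calling,
    an exact Mendelian expectation engine for XX/XO crossing schemes with
    per-class viability and fertility models, phenotype-rate statistics and
    HI classification (embryonic lethality, larval arrest, brood size, male
    sterility and inviability), interval-contrast refinement of candidate HI
    loci, and a backcross simulator that generates realistic synthetic
    inputs for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    IRanges,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
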