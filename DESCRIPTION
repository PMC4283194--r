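Package: petrel
Title: Kinetic Quantification and Test-Retest Reliability for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neuroreceptor availability from dynamic PET
    time-activity curves and measures the test-retest reliability of the
    resulting estimates. Implements seven quantification routes for
    reversible tracers such as the CB1-receptor ligand [11C]MePPEP:
    one- and two-tissue compartmental models with a variable blood volume
    term, classic spectral analysis on regions and voxelwise parametric
    maps, rank-shaping regularised spectral analysis, the simplified
    reference tissue model with a pseudo-reference region, and modified
    standardised uptake values. Includes derivation of metabolite-corrected
    arterial plasma input functions from continuous and discrete blood
    samples, a synthetic-data generator for bolus input functions, tissue
    kinetics, voxel phantoms and two-session cohorts with known ground
    truth, and reliability statistics (signed test-retest percentage
    difference, one-way random single-measures intraclass correlation,
    between-subject coefficient of variation, Bland-Altman comparison,
    binding-heterogeneity ratios).
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
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
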