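Package: serialcna
Title: Copy-Number Dynamics in Serially Biopsied Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-course analysis of allele-specific copy-number profiles from
    serially biopsied tumors under neoadjuvant treatment. Computes genomic
    instability indices and aberration frequency profiles from purity- and
    ploidy-adjusted segment tables, derives clinical response groups from tumor
    shrinkage ratios, tests gene-level adjusted log-ratios for association with
    response after an expression-correlation filter, and tracks clonal and
    subclonal aberration cell fractions across treatment time points with a
    chi-squared genome scan for subclones under positive or negative selection.
    Includes a synthetic-cohort generator emulating ASCAT/Battenberg-style
    inputs with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
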