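Package: senscan
Title: Sensitive-Region Scanning of Missense Variant Density in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-level missense-tolerance profiling for single genes.
    Builds Gaussian-window smoothed per-residue variant-density curves from a
    clinical (ClinVar-style) and a population (gnomAD-style) variant set,
    corrects curve values near the protein termini for the kernel mass that
    falls outside the protein, normalizes both curves to a common maximum,
    and subtracts them to call "sensitive regions" where disease-associated
    missense variation is enriched over population variation. Also classifies
    early-truncating (nonsense and frameshift) variants by the last-exon
    nonsense-mediated-decay rule, assembles haploinsufficiency-tolerance
    reports, renders tolerance-curve and exon-map figures, parses HGVS
    protein notation, and ships a seeded synthetic-data generator plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
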