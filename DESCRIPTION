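Package: dogphen
Title: Forensic DNA Phenotyping of Dogs from a 21-Marker Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts externally visible traits of domestic dogs (coat
    colour, coat pattern, coat structure, body size, ear shape, tail
    length) from genotypes at a panel of 21 published phenotype markers
    (15 SNPs, six insertion/deletion markers of which three are SINE
    insertions). Provides a validated machine-readable panel model,
    readers and writers for genotype tables, VCF, phenotype metadata and
    prediction reports, a Sanger-style base-call trace caller that
    resolves out-of-phase heterozygous insertion traces, a rule engine
    implementing the epistatic dominance hierarchy of the canine
    coat-colour loci (E, K, A, B, D, S, M, H), standardized "identikit"
    trait descriptions, a seeded cohort simulator reproducing the
    documented genotype-phenotype discordance mechanisms, and
    concordance scoring with heatmap-style summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    vcfR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
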