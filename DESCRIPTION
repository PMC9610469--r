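Package: phagetr
Title: Characterization of Tailed Phages with Genome Terminal Repeats in
    Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for characterizing Caudoviricetes
    phage genomes carrying direct or inverted terminal repeats, as
    recovered from total fecal metagenomes. Detects terminal repeats and
    intragenomic repeat pairs (including diversity-generating
    retroelement candidates), assigns alternative genetic codes with
    stop-codon reassignment, applies marker-protein taxonomic decision
    rules, clusters genomes into species-level vOTUs at 95% average
    nucleotide identity, converts read mappings into breadth-gated
    abundances and prevalences, tests longitudinal virome stability with
    a label-permutation test on Bray-Curtis dissimilarities, predicts
    microbial hosts from prophage fragments, CRISPR spacers and
    co-abundance meta-analysis, and scans for host-adjusted
    phage-phenotype associations. A synthetic-data generator with
    planted ground truth makes every stage testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
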