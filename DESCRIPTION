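Package: cpgvar
Title: Classification and Enrichment Analysis of CpG-Site-Related Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying single-nucleotide variants that create or
    abolish CpG dinucleotides (cgSNPs). Classifies biallelic substitutions by
    their effect on CpG presence in the trinucleotide context and orients
    gains and losses with the ancestral allele; annotates positions with
    CpG-island context (island, shore, open sea) and gene context (gene body,
    promoter, intergenic); computes linkage-disequilibrium tagging, cgSNP-tag
    (cgSNPt) status and greedy LD pruning; tests enrichment of cgSNPts among
    eQTLs or trait-associated loci with a covariate-adjusted logistic model
    and a stratified matched-resampling empirical null; and summarises paired
    normal-minus-tumor methylation differences at CpG-destroying somatic
    mutations in distance bins. Ships a seeded synthetic-data generator that
    emits every input format with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
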