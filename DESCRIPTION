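Package: luxscreen
Title: Quorum-Sensing Gene Screening and Lux-Box Regulon Prediction in Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screen for acyl-homoserine-lactone (AHL) quorum-sensing
    genes in assembled metagenomes and for AHL-regulated promoters (lux boxes) in the
    contigs of a target taxon. Classifies ORFs as putative luxI (AHL synthase) or luxR
    (AHL receptor) homologs from KEGG-orthology-labelled protein search hits, validates
    them against conserved Pfam domains, audits LuxR conserved residues by global
    alignment to an annotated reference, resolves cognate luxI/luxR pairs versus luxR
    solos, assigns per-ORF consensus function and lowest-common-ancestor taxonomy from
    best-score hit windows, bins contigs to a target taxon by a tiered ORF-fraction
    rule, and scans 400 bp upstream regions with a position weight matrix trained on an
    aligned lux-box library, using exact dynamic-programming p-values and an
    imperfect-palindrome filter, annotating hits with promoter elements (-35/-10,
    Shine-Dalgarno) and intergenic/intragenic location. Includes a seeded synthetic
    community generator with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
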