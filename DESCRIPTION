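Package: ystrata
Title: Detection of Recombination-Suppression Blocks on Plant Y Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates candidate evolutionary strata on a Y chromosome from
    male/female whole-genome read sets and a phased diploid assembly of a male.
    Canonical k-mers are counted per sample, a male-specific k-mer set is
    derived with per-sample coverage thresholds, contigs of the phased assembly
    are assigned to the Y haplotype by differential k-mer matching, Y-linked
    contigs are segmented into k-mer density blocks with a windowed
    leading/trailing density-ratio scan, and blocks are ordered against an
    annotated reference via best-hit synteny anchors. Includes a seeded
    synthetic-data generator producing ground-truthed diploid read sets and
    phased contigs with planted Y strata for validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
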