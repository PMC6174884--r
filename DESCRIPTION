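Package: crisprStrainScan
Title: Genome-Wide Off-Target and Loss-of-Heterozygosity Assessment for
    CRISPR-Edited Diploid Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the genomic integrity of a CRISPR/Cas9-edited
    diploid microbial strain against its parental wild type from
    whole-genome resequencing derived inputs: guide design checks (GC
    rule, seed region) and exhaustive PAM-constrained off-target search;
    filtering and shared/strain-specific partitioning of per-strain
    variant calls; 50 kb windowed heterozygosity profiling with loess
    smoothing; differential loss-of-heterozygosity (LOH) segment calling
    with variant-level boundary refinement and a read-depth-ratio test
    separating hemizygous deletion from gene conversion; genotype-dosage
    strain similarity (Pearson correlation, Euclidean distance); and
    structural-variant support filtering, class summaries and two-strain
    comparison. A seeded simulator generates diploid strain pairs
    (reference FASTA, per-strain VCFs, coverage tracks, SV tables) with
    planted edits, off-target decoys and LOH tracts plus a machine-readable
    truth table, so every stage can be scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
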