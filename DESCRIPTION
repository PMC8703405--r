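Package: mosaicpaint
Title: Reference-Guided Scaffold Placement and Chromosome Painting of
    Introgressed Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to place de novo assembly scaffolds on a reference genome
    by exact k-mer anchoring and colinear chaining, connect them into
    pseudomolecules with AGP output, compute assembly summary statistics
    (N50, coverage), validate assemblies by locating known genes with a
    seed-and-extend search, classify SNPs from an offspring/two-parent VCF by
    parental origin, paint the offspring genome in fixed windows with a
    dominant-type rule to estimate genome composition, and zoom into a QTL
    region to report contiguous same-origin segments. Includes a synthetic
    mosaic-genome simulator (founders, recombinant offspring, fragmented
    scaffolds, planted genes, trio VCF with truth files) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
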