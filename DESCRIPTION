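Package: multiguide
Title: Multiplexed CRISPR-Cas9 Guide Design, Cloning-Free Template
    Assembly, and Mutant Screening Analytics for Zebrafish
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A design-and-analysis toolkit for multiplexed CRISPR-Cas9
    mutagenesis screens in zebrafish. Scans exon sequences on both strands
    for GG-prefixed protospacers with an NGG protospacer-adjacent motif,
    ranks candidates by proximity to the coding-sequence start, and builds
    the complete 125-nt T7 transcription template for each guide. The
    template is decomposed into three sticky-ended duplex fragments made of
    six 38-46 nt oligonucleotides whose junction overhangs force a unique
    ligation order; an exhaustive ligation simulator verifies that exactly
    one full-length linear product forms and that no circular by-products
    are possible. Downstream, mutant allele sequences from Sanger
    genotyping are aligned to wild type, indel events are called and
    classified (deletion, insertion, complex; frameshift vs in-frame),
    founder cohorts are summarised into per-gene mutation efficiencies and
    event-class distributions, and C-start startle-response screens are
    scored with a latency gate and compared across genotypes, with matched
    synthetic-data generators for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Alignment, Genetics
RoxygenNote: 7.3.3
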