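Package: chipsim
Title: Simulation of ChIP-Seq Experiments with Learnable Model Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation of chromatin-immunoprecipitation sequencing
    (ChIP-seq) experiments. Models the four key experimental steps as distinct
    stochastic modules: shearing of genomic DNA into gamma-distributed fragment
    lengths, antibody pulldown with an enrichment ratio for bound versus
    unbound fragments, PCR amplification with geometric duplicate
    multiplicities, and single- or paired-end sequencing with per-base
    substitution, insertion and deletion errors. Emits raw reads in FASTQ
    format from a reference genome (FASTA) and a scored peak set (BED).
    A companion learning component infers every model parameter from an
    existing aligned ChIP-seq dataset: gamma fragment-length parameters from
    paired-end template lengths (or a strand cross-correlation heuristic for
    single-end data), the bound genome fraction from scored peaks, the
    fraction of reads in peaks, and the PCR duplicate rate from the duplicate
    multiplicity histogram. Includes evaluation utilities (binned read-count
    correlation, peak-set precision/recall) and deterministic toy-data
    generators so all examples run without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    stringi,
    withr,
    fitdistrplus,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    Rsamtools,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
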