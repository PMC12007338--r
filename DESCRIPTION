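Package: refpolish
Title: Reference-Comparative Error Detection and Correction for Long-Read Draft Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and corrects gene-fragmenting small indel and substitution
    errors in small-genome long-read draft assemblies by comparing the draft
    against a curated set of related reference genomes aligned to it. Columns
    where all (or a configurable fraction of) aligned references disagree with
    the draft are scored with a homopolymer-weighted site score over a
    multi-pass window schedule; candidate errors are then confirmed, relocated
    or discarded using raw-read pileup support, and the finalized edit list is
    applied to the assembly. Includes a seeded synthetic-world generator
    (truth genome, divergent references, error-injected draft, simulated
    reads, all serialized as FASTA and samtools mpileup text) so the whole
    workflow is testable without an aligner, plus error-context profiling of
    upstream k-mers and homopolymer lengths.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
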