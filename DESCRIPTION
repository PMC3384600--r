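Package: pseudofuse
Title: Fusion Transcript Discovery from RNA-Seq Reads by Pseudo Paired-End
    Splitting
Version: 0.9.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate fusion transcripts from single-end (or
    paired-end treated as single-end) RNA-Seq reads. Full-length reads that
    fail to align to a coding reference transcriptome are split into pseudo
    paired-end mates which are aligned independently; mate pairs hitting two
    different genes are carried through a six-stage false-positive filter
    cascade (same-gene, unaligned, paralog, antisense, insert geometry,
    multi-mapping), merged into genomic alignment blocks, resolved to their
    nearest annotated exons, enumerated as fusion isoforms and categorised
    (interchromosomal, intrachromosomal, potential read-through, inversion).
    Ships a deterministic built-in seed aligner, a synthetic transcriptome
    and read simulator with planted fusions, and sensitivity/PPV evaluation
    with synonymous-fusion accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
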