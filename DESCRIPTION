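Package: blotprobe
Title: Automated Design of Southern Blot Probes from Soft-Masked Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs unique hybridization probes (500-1300 bp) for Southern
    blotting against a soft-masked genome assembly. Candidate probes are
    enumerated by fractional-step tiling of a user-specified genomic window,
    searched against the genome with an affine-gap local aligner (k-mer seeded
    or exhaustive), and scored by uniqueness (self-hit to second-hit score
    ratio) and repetitive/low-complexity content (soft-masked base fraction).
    Candidates are binned into unique/passed/failed groups, redundant probes
    removed, cut-offs relaxed automatically at difficult loci, and PCR
    recovery primers picked by nearest-neighbor thermodynamics. Includes a
    deterministic synthetic soft-masked genome generator with ground truth,
    an on-disk resumable pipeline store, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
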