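Package: wavealign
Title: Actor-Based Wavefront-Parallel Smith-Waterman Local Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local pairwise sequence alignment with Gotoh affine or linear gap
    penalties, parallelized at two levels on top of a minimal actor runtime:
    across independent pair alignments (a manager actor dispatching tasks to
    pair actors) and within a single alignment (block actors computing
    rectangular tiles of the dynamic-programming score matrix in antidiagonal
    wavefront order). Includes a serial reference kernel with full traceback
    and CIGAR output, FASTA input and TSV/pretty result output, a command-line
    interface, and a seeded synthetic dataset generator so the whole stack is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    utils,
    stats,
    Biostrings,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
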