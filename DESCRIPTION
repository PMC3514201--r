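Package: seedasm
Title: Targeted Micro-Assembly of Short Sequencing Reads Around Starter Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Checks whether user-supplied starter sequences are supported by a
    set of unassembled short sequencing reads (read coherence), enumerates the
    perfect-consensus variants of each starter within a bounded Hamming
    distance (sub-starters), and performs iterative targeted micro-assembly
    around each sub-starter. Reads are streamed against a k-mer index of the
    starters so memory never scales with the read file; mapped reads are
    error-corrected by per-column voting. Results are returned either as a
    consensus sequence with per-position read coverage or as a rooted
    extension graph whose branches expose SNPs, repeats, splice or fusion
    junctions, exportable as GraphML or XGMML. Seeded simulators for shotgun
    reads with substitution errors, planted variant sites and repeat contexts
    are included for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
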