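Package: dupsweep
Title: Segmental Duplication Detection and Decomposition in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects segmental duplications (SDs) in hard-masked genome
    assemblies at up to 25 percent sequence divergence using a plane sweep
    over a winnowed k-mer index with an ordered Jaccard filter, refines
    candidate region pairs into validated SD calls by anchor chaining and
    banded alignment, decomposes SD sets into elementary SDs and core
    duplicons, maps SDs across multiple assemblies, and ships a simulator
    implementing a two-component (point mutation plus block edit) SD error
    model for sensitivity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
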