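Package: coalsplit
Title: Two-Population Coalescent Simulation and the TMRCA Versus
    Divergence-Time Distinction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates gene genealogies under a two-population isolation
    model (a single backward-in-time population join, no migration) with an
    infinite-sites mutation overlay, in the ms command dialect. Provides
    tree analytics (TMRCA of a leaf subset, root height, basal-node age,
    monophyly classification), exact coalescent oracles (ancestral
    lineage-count distribution, single-outgroup monophyly probability,
    Watterson expectations), scenario experiments contrasting the TMRCA of
    a densely sampled taxon with its divergence date from a sister lineage,
    and a recombination-masking/SNP-culling utility for whole-genome
    alignments with ClonalFrameML-style importation intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
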