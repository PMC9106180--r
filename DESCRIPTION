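Package: telorepair
Title: Simulation and Quantification of UV Photoproduct Repair Kinetics in
    Yeast Subtelomeres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying nucleotide excision repair (NER) of
    ultraviolet-light-induced DNA photoproducts at Saccharomyces cerevisiae
    chromosome ends. Builds annotated synthetic subtelomeric loci (X- and
    Y'-elements, terminal C1-3A/TG1-3 repeats), scans strand-specific
    dipyrimidine sites, performs in-silico restriction digestion, and
    simulates the two classic gel assays: T4 endonuclease V Southern blots
    of cyclobutane pyrimidine dimers (CPDs) and Taq-polymerase-stop primer
    extension ladders of pyrimidine dimers. Lesion formation is modelled as
    an independent per-site process calibrated to target CPD densities, and
    repair as strain-dependent exponential removal combining global genome
    repair, Rad26-dependent transcription-coupled repair and Sir2-dependent
    chromatin accessibility. Analysis functions recover CPD densities from
    band ratios via the Poisson zero-class estimator, compute
    background-corrected photoproduct frequencies and percent-repair time
    courses, aggregate dimer clusters, and compare strains with two-way
    ANOVA and Sidak-adjusted per-time contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
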