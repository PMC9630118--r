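Package: numtatlas
Title: Detection and Characterization of Nuclear-Embedded Mitochondrial DNA
    Segments from Short-Read Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering NUMTs (nuclear-embedded
    mitochondrial DNA segments) that are absent from the reference assembly,
    from paired-end whole-genome alignments. Calls candidate insertions from
    nuclear-mitochondrial discordant read pairs, refines breakpoints from
    soft-clipped split reads, classifies junction repair mechanism
    (microhomology, blunt, insertion), detects concatenated NUMTs via
    mtDNA-mtDNA junctions, unifies calls across a cohort with population
    frequency classes, calls de novo (trio) and tumour-specific events with
    exact binomial insertion-rate estimates, runs permutation enrichment of
    insertion sites against annotation tracks, and analyses post-insertion
    molecular evolution (consensus assembly, NUMT-specific variants, 96-class
    mutational spectra, ancestral-allele-ratio ages). Includes a deterministic
    synthetic-cohort generator with machine-readable truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
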