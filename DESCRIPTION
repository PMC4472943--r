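Package: episttp
Title: Epistasis Analysis of DUSP1 and Tristetraprolin Control of
    LPS-Induced Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much of the effect of Dusp1 deletion on
    LPS-induced macrophage transcripts is mediated by phosphorylation of
    tristetraprolin (TTP, Zfp36), using a four-genotype factorial
    expression design. Implements per-transcript DUSP1 effects in two
    Zfp36 backgrounds (DE1, DE2), a replicate-based test of DE1 = DE2,
    and a through-origin regression of DE2 on DE1 against the
    no-epistasis diagonal, with an optional errors-in-variables
    attenuation correction. Supporting stages cover microarray probe
    filtering, per-probe two-way ANOVA with Benjamini-Hochberg step-up
    FDR, LPS-induction summaries, hierarchical clustering of expression
    profiles, first-order mRNA decay fitting from transcription-shutoff
    chases, delta-delta-Ct relative quantification, and AU-rich element
    (UAUUUAU) scanning of 3' UTRs. A seeded synthetic-data generator with
    known ground truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
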