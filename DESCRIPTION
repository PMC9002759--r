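Package: awbox
Title: AW-Box Motif Scanning and WRI1-Binding Classification for Plant Promoters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of the AW box, the 14-bp cis-regulatory
    element (CNTNG(N)7CG) bound by the WRINKLED1 (WRI1) transcription factor
    upstream of plant fatty-acid biosynthesis genes. Provides a no-zero
    translation-initiation-site (TIS) coordinate system, strand-aware scanning
    of promoter sequences for canonical and single-insertion ("extra base")
    AW boxes, position frequency/probability/weight matrix construction from
    electrophoretic-mobility-shift-assay (EMSA) bound motif sets,
    forbidden-base and base-bias detection at the variable N positions,
    IUPAC degenerate consensus derivation, a rule-based WRI1-bindability
    classifier, a packaged sunflower AW-box inventory with EMSA labels, and a
    seeded synthetic promoter generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: MotifAnnotation, SequenceMatching, Transcription, GeneRegulation
RoxygenNote: 7.3.3
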