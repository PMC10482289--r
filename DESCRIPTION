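Package: pprcue
Title: PPR-RNA Code Matching and C-to-U RNA Editing Off-Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying PLS-type pentatricopeptide repeat (PPR) RNA
    editing factors such as the moss factor PPR56 in heterologous expression
    systems. Models PPR arrays with their position 5 / position Last amino
    acid identities, evaluates PPR-RNA recognition code matches against
    target windows, scans transcript sequences for candidate C-to-U editing
    sites, and classifies alignment shifts. Implements the mutation and
    editing-site nomenclatures used for such factors (protein-domain point
    mutations, PPR 5/Last shorthand, target substitutions, eU site labels),
    a replicate-supported off-target caller for per-site RNA/DNA base-count
    tables with a four-criterion filter cascade and control exclusion,
    efficiency-weighted nucleotide profiles with information content for
    sequence logos, and a fully seeded synthetic-data generator producing
    reference sequences, planted editing sites, per-dataset count tables and
    Sanger peak pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
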