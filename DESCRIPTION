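Package: orfgenesis
Title: Tracing the Evolutionary Genesis of De Novo Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing how a de novo open reading frame (ORF)
    and its linked transcriptional silencer emerge from ancestrally non-coding
    sequence along a species panel ordered by divergence age. Implements
    synteny-guided homolog location using a conserved guidepost ORF,
    translated-frame similarity detection of an early developmental peptide,
    twilight-zone classification of per-species similarity calls with
    Karlin-Altschul Expect values, root-species inference, classification of
    substitutions as evolutionarily fixed (biased) versus lineage-specific
    (random), wobble-position analysis, slipped-strand repeat event detection,
    and a ground-truthed simulator of seeded, nearest-neighbour ORF growth.
    Ships the human SMIM45 exon 2 sequences (68 aa ORF, silencer
    LOC130067579, intervening sequence, 107 aa ORF) as worked fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
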