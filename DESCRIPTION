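Package: crescan
Title: Conserved Sequence Detection and Cis-Regulatory Element Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fully conserved nucleotide patterns (>= 15 nt, 100%
    column identity) in multiple alignments of orthologous intron and exon
    sequences from mammalian species, then annotates the patterns with
    putative cis-regulatory elements: transcription-factor binding sites
    scored by position-weight-matrix log-odds against a CIS-BP-style motif
    library, and donor/acceptor splice signals scored by a min-max
    normalised consensus value and an optional maximum-entropy model.
    Patterns are classified into TFBS / TFBS-SS / SS / not-identified
    groups, summarised per intron, tallied by binding-domain family, and
    compared against matched non-conserved control sequences with
    Mann-Whitney, Chi-square and paired Wilcoxon tests. A synthetic-data
    simulator generates fully specified orthologous gene regions with
    planted conserved blocks, motifs and splice sites so the entire
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
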