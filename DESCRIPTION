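Package: tecurate
Title: Transposable Element Consensus Curation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated curation of transposable element (TE) consensus
    libraries: mining genomic copies of a draft consensus (seed-and-extend
    search or imported hit tables), flank extension and oriented extraction,
    anchored star alignment, majority-rule IUPAC consensus building with
    indel-event handling and placeholder insertion, detection of element
    termini and structural hallmarks (terminal inverted repeats, long terminal
    repeats, target site duplications and target-site models, boundary
    sequence logos), RepeatMasker-style classification and nomenclature
    validation, library comparison under the 80-80-80 and 95-80-98 rules,
    annotation statistics (Kimura 2-parameter divergence, repeat landscapes,
    masked fractions, putatively-active subfamily filter), a peer-review and
    versioning ledger, and a synthetic-genome simulator with implanted TE
    families for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
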