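Package: zfclass
Title: Classification of Gli/Glis/Nkl/Zic C2H2 Zinc-Finger Superfamily Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects tandem C2H2 zinc-finger architectures in protein
    sequences, applies the ZF1 inter-cysteine-spacing diagnostic and
    ZOC / ZF-NC consensus-motif scoring that distinguish the Zic
    sub-family from Gli, Glis and Nkl, assigns sub-family labels with a
    neighbor-joining placement against a labelled reference panel, and
    evaluates gene-family-origin scenarios on a rooted species tree by
    Dollo parsimony gain/loss counting. Includes a seeded synthetic
    generator of superfamily-like proteins with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
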