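Package: ppzcompare
Title: Comparative Conservation Profiling of PP1 and PPZ Phosphatases and
    BS3 Cross-Link Mapping
Version: 0.1.0
Authors@R:
    person("ppzcompare", "developers", email = "ppzcompare@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of fungal type 1 (PP1) and
    type Z (PPZ) Ser/Thr protein phosphatases and for desk-scale chemical
    cross-linking mass spectrometry. One arm profiles a joint multiple
    sequence alignment of two ortholog groups column by column, classifies
    group-differential positions into conservation classes, scans for
    charge-category swaps, reports docking-motif conservation, computes
    Shannon sequence-logo matrices, pairwise identities and a
    neighbor-joining phylogram. The other arm identifies BS3 (lysine-lysine)
    cross-links from MGF peak lists: scan filtering by charge and signature
    ions, in-silico tryptic digestion with missed cleavages, precursor-mass
    candidate enumeration at ppm tolerance, theoretical b/y fragment
    matching and a both-peptides validation rule, plus a bidimensional
    contact map of cross-linked residues. Ground-truthed synthetic-data
    generators cover both arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
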