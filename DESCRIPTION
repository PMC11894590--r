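Package: degradome
Title: In Silico Proteolytic Degradome Atlases for Protein Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration and annotation of partial proteolytic
    cleavage products. Detects protease and chemical cleavage sites from a
    transcribed PeptideCutter-style specificity table, enumerates every
    boundary-delimited peptide (all missed-cleavage products) of a protein
    panel, deduplicates and classifies peptide sequences as pan-panel or
    isoform-unique, computes physicochemical indices (Boman, aliphatic,
    instability, GRAVY, charge, isoelectric point, average mass and [M+H]+
    m/z), summarises peptide pools, and quantifies how point mutations or
    selective enzyme inhibition reshape the peptide pool. Ships the five
    human neurofilament intermediate-filament subunits (NfH, NfM, NfL,
    alpha-internexin, peripherin) as a built-in panel.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
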