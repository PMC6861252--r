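Package: invorigin
Title: Inversion Origin Mechanisms and Breakpoint-Flanking Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the origin of chromosomal inversions whose breakpoints
    share a duplicated flanking fragment, after the E chromosome inversion
    complex of Drosophila subobscura. Represents arrangements as ordered
    oriented fragments, implements cut-and-paste, isochromatid, chromatid and
    three heterokaryotype repair models (NHEJ with four or three breaks, and
    BIR-NHEJ) together with their testable genealogical predictions, and
    provides a coalescent-style simulator of breakpoint-flanking alignments
    plus a self-contained population-genetics stack: nucleotide diversity,
    segregating-site and haplotype summaries, Jukes-Cantor distances, Hudson
    F_ST with permutation tests, neighbor-joining trees with bootstrap
    support, and a concordance verdict comparing the molecular genealogy with
    the cytological phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
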