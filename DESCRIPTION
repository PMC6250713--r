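Package: npmine
Title: Neuropeptide Precursor Mining and Prohormone Processing Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and structural annotation of neuropeptide precursor
    (prepropeptide) genes in insect transcriptome and genome assemblies.
    Implements a six-frame translated Smith-Waterman homology search against
    a reference precursor panel, rule-based prediction of prohormone
    convertase cleavage sites (mono-, di- and tetrabasic K/R motifs),
    signal-peptide detection, inference of C-terminal amidation and
    N-terminal pyroglutamate, neuropeptide-family motif censuses
    (paracopy counting), reciprocal-best-hit orthology, and matching of
    predicted mature peptides against observed MALDI-TOF masses via
    monoisotopic b/y fragment ladders. Ships a synthetic-data generator
    that emulates precursor architectures with full ground truth, so the
    whole pipeline is testable end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
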