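# Hand-built fixture objects (constructed in code, no files).

make_pep <- function(seq, amidated = FALSE, copy_index = 1L,
                     precursor = "p") {
  structure(list(seq = seq, start = 0L, end = nchar(seq),
                 amidated = amidated, pyroglutamate = startsWith(seq, "Q"),
                 fragment = nchar(seq) < 3L, copy_index = copy_index,
                 precursor = precursor),
            class = "mature_peptide")
}

make_model <- function(peptides, id = "p", family = NULL) {
  structure(list(protein = protein_record(id, strrep("A", 20)),
                 signal = NULL, sites = list(), peptides = peptides,
                 flags = list(complete_n_terminus = FALSE,
                              complete_c_terminus = TRUE),
                 family = family),
            class = "precursor_model")
}
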