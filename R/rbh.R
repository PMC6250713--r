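# Reciprocal-best-hit (RBH) orthology between two proteomes.

#' Reciprocal-best-hit ortholog pairs
#'
#' For every protein in `proteome_a` the best-scoring local alignment in
#' `proteome_b` is found, and vice versa; a pair is flagged reciprocal when
#' the two searches pick each other. Score ties are broken by lexicographic
#' subject id, deterministically.
#'
#' @param proteome_a,proteome_b Lists of [protein_record()]s.
#' @param scheme A [scoring_scheme()].
#' @param min_score Pairs scoring below this in the a->b direction are
#'   dropped.
#' @return A data frame with one row per member of `proteome_a` that has a
#'   best hit: `id_a`, `id_b`, `score_ab`, `score_ba`, `reciprocal`.
#' @export
rbh_orthologs <- function(proteome_a, proteome_b, scheme = scoring_scheme(),
                          min_score = 0L) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("both proteomes must be non-empty")
  ids_a <- record_ids(proteome_a)
  ids_b <- record_ids(proteome_b)
  go <- -scheme$gap_open; ge <- -scheme$gap_extend
  ca <- lapply(proteome_a, function(p) encode_aa(p$seq, scheme))
  cb <- lapply(proteome_b, function(p) encode_aa(p$seq, scheme))
  S <- matrix(0L, length(ca), length(cb))
  for (i in seq_along(ca))
    for (j in seq_along(cb))
      S[i, j] <- sw_score_cpp(ca[[i]], cb[[j]], scheme$matrix, go, ge)
  best_b <- apply(S, 1L, function(row) best_index(row, ids_b))
  best_a <- apply(S, 2L, function(col) best_index(col, ids_a))
  rows <- lapply(seq_along(ca), function(i) {
    j <- best_b[i]
    if (S[i, j] < min_score) return(NULL)
    data.frame(id_a = ids_a[i], id_b = ids_b[j],
               score_ab = S[i, j], score_ba = S[best_a[j], j],
               reciprocal = best_a[j] == i, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      score_ab = integer(), score_ba = integer(),
                      reciprocal = logical(), stringsAsFactors = FALSE)
  out
}

# index of the maximum, ties broken by lexicographic id
best_index <- function(scores, ids) {
  cand <- which(scores == max(scores))
  cand[order(ids[cand])][1]
}
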