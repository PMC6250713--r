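# Ground-truth evaluation of mining and MS matching on synthetic data.

#' Evaluate mining results against a ground-truth ledger
#'
#' A true locus counts as recovered when some hit lands on its transcript
#' in the correct frame with nucleotide overlap of the embedded CDS.
#' Hits on decoy transcripts count as false acceptances.
#'
#' @param results Output of [mine_sequences()].
#' @param truth The `truth` element of [generate_dataset()].
#' @return A list: `recall`, `precision`, `n_true`, `n_recovered`,
#'   `decoy_hits`, `n_hits`.
#' @export
evaluate_mining <- function(results, truth) {
  tx <- truth$transcripts
  true_tx <- Filter(function(t) !isTRUE(t$decoy), tx)
  decoy_ids <- vapply(Filter(function(t) isTRUE(t$decoy), tx),
                      function(t) t$id, character(1))
  ht <- hits_table(results)
  recovered <- vapply(true_tx, function(t) {
    sel <- ht$sid == t$id & ht$frame == t$frame &
      ht$sstart < t$end & ht$send > t$start
    any(sel)
  }, logical(1))
  decoy_hits <- sum(ht$sid %in% decoy_ids)
  n_true <- length(true_tx)
  list(recall = if (n_true) mean(recovered) else NA_real_,
       precision = if (nrow(ht)) 1 - decoy_hits / nrow(ht) else NA_real_,
       n_true = n_true, n_recovered = sum(recovered),
       decoy_hits = decoy_hits, n_hits = nrow(ht))
}

#' Evaluate MS re-identification against the generating peptides
#'
#' An observation is correctly re-identified when its top-ranked match has
#' the generating peptide's sequence and modification state.
#'
#' @param matches Output of [match_observations()].
#' @param obs_truth The `obs_truth` element of [generate_dataset()].
#' @return A list: `rate`, `n_obs`, `n_correct`.
#' @export
evaluate_ms_roundtrip <- function(matches, obs_truth) {
  n_obs <- nrow(obs_truth)
  correct <- vapply(seq_len(n_obs), function(oi) {
    top <- matches[matches$obs_index == oi & matches$rank == 1L, ,
                   drop = FALSE]
    if (!nrow(top)) return(FALSE)
    t <- obs_truth[oi, ]
    top$seq[1] == t$seq && top$amidated[1] == t$amidated &&
      top$pyroglutamate[1] == t$pyroglutamate &&
      top$c_term_truncation[1] == t$c_term_truncation
  }, logical(1))
  list(rate = mean(correct), n_obs = n_obs, n_correct = sum(correct))
}
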