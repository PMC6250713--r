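# Heuristic signal-peptide prediction.
#
# A rule-based stand-in for dedicated predictors: a candidate cleavage
# position must satisfy the classical (-3,-1) small-residue rule and the
# N-terminal region must contain a sufficiently hydrophobic core (best
# 8-residue Kyte-Doolittle window). An externally computed span (e.g. from
# a dedicated predictor's output) can be passed to [annotate_precursor()]
# and overrides this heuristic.

#' Predict a signal peptide
#'
#' Scans cleavage positions 15..45 (the span covers the common insect
#' signal-peptide lengths). A position `end` is a candidate when the
#' residues at `end-3` and `end-1` (1-based) are small/neutral
#' (`A,G,S,C,T,V`) and the mean Kyte-Doolittle hydropathy of the best
#' 8-residue window within residues 3..`end-4` is at least `min_core_kd`.
#' The candidate with the highest hydrophobic-core score wins; ties go to
#' the earliest position.
#'
#' @param p A [protein_record()] or amino-acid string, length >= 15.
#' @param min_core_kd Minimum mean hydropathy of the core window
#'   (default 1.6).
#' @return A list with `start` (always 0), `end` (0-based half-open, i.e.
#'   cleavage after residue `end`), and `score`, or `NULL` when no position
#'   qualifies (the precursor is then flagged N-terminally incomplete).
#' @export
predict_signal_peptide <- function(p, min_core_kd = 1.6) {
  seq <- if (inherits(p, "protein_record")) p$seq else p
  seq <- sub("\\*$", "", seq)
  n <- nchar(seq)
  if (n < 15L) return(NULL)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  kd <- unname(KD_HYDROPATHY[aa])
  kd[is.na(kd)] <- 0 # X
  best <- NULL
  for (end in 15L:min(45L, n - 1L)) {
    if (!(aa[end - 2L] %in% SIGNAL_SMALL) || !(aa[end] %in% SIGNAL_SMALL))
      next
    win_to <- end - 4L
    if (win_to - 3L + 1L < 8L) next
    core <- best_window_mean(kd[3L:win_to], 8L)
    if (core < min_core_kd) next
    if (is.null(best) || core > best$score)
      best <- list(start = 0L, end = end, score = core)
  }
  best
}

best_window_mean <- function(x, w) {
  if (length(x) < w) return(-Inf)
  cs <- cumsum(c(0, x))
  max(cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) / w
}
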