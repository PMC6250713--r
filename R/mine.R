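# Translated homology mining: six-frame Smith-Waterman search of a
# transcript set against a reference precursor panel, with score/identity
# thresholds calibrated on an empirical null (shuffled decoys).

#' Mine a transcript set for precursor homologs
#'
#' Each subject transcript is translated in six frames and searched against
#' every panel member. Hits passing the score and identity thresholds are
#' extended to their maximal enclosing open reading frame; one hit, the best
#' scoring, is reported per (subject, family).
#'
#' @param subjects List of [transcript_record()]s.
#' @param panel List of [protein_record()] queries (the reference precursor
#'   panel).
#' @param families Character vector assigning each panel member to a family;
#'   defaults to the panel descriptions (falling back to ids).
#' @param scheme A [scoring_scheme()].
#' @param min_score Minimum alignment score (see [calibrate_min_score()]).
#' @param min_identity Minimum fraction of identical alignment columns.
#' @param min_orf_aa Minimum length of the enclosing ORF, in residues.
#' @param max_rounds Maximum number of mining rounds. After each round the
#'   proteins of newly accepted loci are appended to the panel (under the
#'   family that found them) and mining repeats until no new locus appears.
#' @param table Codon table for translation.
#' @return A list of results sorted by decreasing score, each a list with
#'   `hit` (an `alignment_hit` with `frame` and `subject_nt_span` filled)
#'   and `orf` (the enclosing `orf_call`, or `NULL` if none passed
#'   `min_orf_aa`), plus `family`.
#' @export
mine_sequences <- function(subjects, panel, families = NULL,
                           scheme = scoring_scheme(), min_score = 50L,
                           min_identity = 0.3, min_orf_aa = 30L,
                           max_rounds = 1L, table = "1") {
  if (!length(panel)) stop("reference panel is empty")
  families <- families %||% panel_families(panel)
  accepted <- list() # keyed subject\rfamily
  for (round in seq_len(max_rounds)) {
    res <- mine_round(subjects, panel, families, scheme, min_score,
                      min_identity, min_orf_aa, table)
    new <- res[!names(res) %in% names(accepted)]
    accepted[names(new)] <- new
    if (!length(new) || round == max_rounds) break
    for (r in new) {
      if (!is.null(r$orf)) {
        panel <- c(panel, list(r$orf$protein))
        families <- c(families, r$family)
      }
    }
  }
  out <- unname(accepted)
  out[order(-vapply(out, function(r) r$hit$score, numeric(1)),
            vapply(out, function(r) r$hit$subject, character(1)))]
}

panel_families <- function(panel) {
  fam <- vapply(panel, function(p) p$description %||% "", character(1))
  ifelse(nzchar(fam), fam, record_ids(panel))
}

mine_round <- function(subjects, panel, families, scheme, min_score,
                       min_identity, min_orf_aa, table) {
  go <- -scheme$gap_open; ge <- -scheme$gap_extend
  qcodes <- lapply(panel, function(p) encode_aa(p$seq, scheme))
  results <- list()
  for (subj in subjects) {
    frames <- six_frame_translate(subj, table)
    fcodes <- lapply(frames, function(f) encode_aa(f$seq, scheme))
    # best score per family over all (query, frame) pairs
    best <- list()
    for (qi in seq_along(panel)) {
      fam <- families[qi]
      for (fi in seq_along(frames)) {
        if (!length(fcodes[[fi]])) next
        sc <- sw_score_cpp(qcodes[[qi]], fcodes[[fi]], scheme$matrix, go, ge)
        b <- best[[fam]]
        if (is.null(b) || sc > b$score)
          best[[fam]] <- list(score = sc, qi = qi, fi = fi)
      }
    }
    if (!length(best)) next
    orfs <- NULL
    for (fam in names(best)) {
      b <- best[[fam]]
      if (b$score < min_score) next
      hit <- sw_align(panel[[b$qi]], frames[[b$fi]], scheme)
      if (hit$identity < min_identity) next
      origin <- frames[[b$fi]]$origin
      L <- nchar(subj$seq)
      nt1 <- codon_coords(origin, hit$subject_span[1], L)
      nt2 <- codon_coords(origin, hit$subject_span[2] - 1L, L)
      hit$frame <- origin$frame
      hit$subject <- subj$id
      hit$subject_nt_span <- c(min(nt1, nt2), max(nt1, nt2))
      if (is.null(orfs)) orfs <- find_orfs(subj, min_orf_aa, table)
      orf <- enclosing_orf(orfs, origin$frame, hit$subject_nt_span)
      key <- paste0(subj$id, "\r", fam)
      results[[key]] <- list(hit = hit, orf = orf, family = fam)
    }
  }
  results
}

# the ORF in the given frame with maximal overlap of the hit's nt span
enclosing_orf <- function(orfs, frame, nt_span) {
  same <- Filter(function(o) o$frame == frame, orfs)
  if (!length(same)) return(NULL)
  ov <- vapply(same, function(o)
    max(0L, min(o$end, nt_span[2]) - max(o$start, nt_span[1])), integer(1))
  if (max(ov) <= 0L) return(NULL)
  same[[which.max(ov)]]
}

#' Calibrate the mining score threshold on an empirical null
#'
#' Scores a set of null transcripts (typically dinucleotide-shuffled
#' versions of the subject transcriptome) against the panel. The
#' per-transcript maxima of local-alignment scores under the null are
#' extreme values, so a Gumbel distribution is fitted to them (method of
#' moments) and the threshold is the level at which the probability that
#' any of `n_searches` null transcripts reaches it is `alpha` - i.e. a
#' family-wise error control over the intended search. The observed null
#' maximum is never undercut.
#'
#' @param panel List of protein records (queries).
#' @param null_transcripts List of transcript records drawn from the null.
#' @param scheme A [scoring_scheme()].
#' @param n_searches Number of transcripts the threshold must protect
#'   (defaults to the null size).
#' @param alpha Tolerated probability of any false acceptance (default
#'   0.001).
#' @param table Codon table.
#' @return A list with `min_score` (the calibrated threshold), `null_max`,
#'   `gumbel` (location/scale), and `scores` (the per-transcript null
#'   maxima).
#' @export
calibrate_min_score <- function(panel, null_transcripts,
                                scheme = scoring_scheme(),
                                n_searches = length(null_transcripts),
                                alpha = 0.001, table = "1") {
  go <- -scheme$gap_open; ge <- -scheme$gap_extend
  qcodes <- lapply(panel, function(p) encode_aa(p$seq, scheme))
  scores <- vapply(null_transcripts, function(subj) {
    frames <- six_frame_translate(subj, table)
    mx <- 0L
    for (f in frames) {
      if (!nzchar(f$seq)) next
      fc <- encode_aa(f$seq, scheme)
      for (qc in qcodes)
        mx <- max(mx, sw_score_cpp(qc, fc, scheme$matrix, go, ge))
    }
    mx
  }, integer(1))
  beta <- stats::sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  p_per <- (1 - alpha)^(1 / n_searches)
  thr <- if (beta > 0) mu - beta * log(-log(p_per)) else mu
  list(min_score = as.integer(ceiling(max(thr, max(scores) + 1))),
       null_max = max(scores),
       gumbel = c(location = mu, scale = beta), scores = scores)
}

#' Tabulate mining hits (BLAST outfmt-6-like)
#'
#' @param results Output of [mine_sequences()].
#' @return A data frame with columns qid, sid, family, pident, length,
#'   qstart, qend, sstart, send, score, frame (coordinates 0-based
#'   half-open; sstart/send are nucleotide positions on the subject).
#' @export
hits_table <- function(results) {
  if (!length(results))
    return(data.frame(qid = character(), sid = character(),
                      family = character(), pident = numeric(),
                      length = integer(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      score = integer(), frame = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(results, function(r) {
    h <- r$hit
    data.frame(qid = h$query, sid = h$subject, family = r$family,
               pident = round(h$identity, 4), length = nchar(h$aligned_query),
               qstart = h$query_span[1], qend = h$query_span[2],
               sstart = h$subject_nt_span[1], send = h$subject_nt_span[2],
               score = h$score, frame = h$frame, stringsAsFactors = FALSE)
  }))
}

#' Export mining hits as GFF3 features on the subject transcripts
#'
#' @param results Output of [mine_sequences()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(results, path) {
  lines <- c("##gff-version 3", vapply(results, function(r) {
    h <- r$hit
    paste(h$subject, "npmine", "protein_match",
          h$subject_nt_span[1] + 1L, h$subject_nt_span[2],
          h$score, if (h$frame > 0) "+" else "-", ".",
          paste0("ID=", h$subject, ":", r$family, ";query=", h$query,
                 ";identity=", round(h$identity, 4)),
          sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
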