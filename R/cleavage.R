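# Rule-based prediction of prohormone convertase cleavage sites.
#
# The engine codifies the classical basic-residue rules used for insect
# prepropeptide annotation: contiguous K/R runs are collapsed into a single
# site at the run's C-terminal end; dibasic pairs KR/RR/RK are cleaved (KK
# optional); a lone R is cleaved only when another basic residue sits at
# position -4, -6 or -8 from the scissile bond; a lone K never; proline
# immediately C-terminal to the bond blocks cleavage; no site falls inside
# or within a short buffer after the signal peptide.

#' Cleavage rule configuration
#'
#' @param dibasic Dibasic motifs cleaved (terminal pair of a 2-residue run).
#' @param cleave_kk Also cleave KK pairs (off by default).
#' @param monobasic_r Allow monobasic R sites (with basic support upstream).
#' @param monobasic_offsets Offsets (residues from the scissile bond) at
#'   which a supporting K/R licenses a monobasic R site.
#' @param block_proline No cleavage when the residue at +1 is proline.
#' @param signal_buffer No site within this many residues after the signal
#'   peptide.
#' @param fragment_min Peptides shorter than this (after trimming) are kept
#'   but flagged `fragment`.
#' @param pyroglu_from_e Also call pyroglutamate for N-terminal Glu
#'   (off by default; only pQ-from-Gln forms are called otherwise).
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(dibasic = c("KR", "RR", "RK"), cleave_kk = FALSE,
                        monobasic_r = TRUE, monobasic_offsets = c(4L, 6L, 8L),
                        block_proline = TRUE, signal_buffer = 3L,
                        fragment_min = 3L, pyroglu_from_e = FALSE) {
  structure(list(dibasic = dibasic, cleave_kk = cleave_kk,
                 monobasic_r = monobasic_r,
                 monobasic_offsets = as.integer(monobasic_offsets),
                 block_proline = block_proline,
                 signal_buffer = as.integer(signal_buffer),
                 fragment_min = as.integer(fragment_min),
                 pyroglu_from_e = pyroglu_from_e),
            class = "rule_config")
}

#' Predict convertase cleavage sites on a precursor
#'
#' @param p A [protein_record()] or amino-acid string (a trailing `*` is
#'   ignored).
#' @param signal Optional signal span (list with `end`) from
#'   [predict_signal_peptide()]; sites inside it or within
#'   `rules$signal_buffer` residues after it are suppressed.
#' @param rules A [rule_config()].
#' @return A list of `cleavage_site` objects, positions strictly
#'   increasing. Each has `position` (0-based index of the first residue
#'   C-terminal to the scissile bond), `kind` (`"monobasic"`, `"dibasic"`,
#'   `"tetrabasic"` for runs of 3 or more, or `"terminus"`), `motif` (the
#'   basic run, e.g. `"KR"`), and `basic_run` (number of contiguous K/R
#'   consumed). The precursor C-terminus is always present as a final site
#'   (kind `"terminus"`) unless a basic site already falls there.
#' @export
predict_cleavage_sites <- function(p, signal = NULL, rules = rule_config()) {
  seq <- if (inherits(p, "protein_record")) p$seq else p
  seq <- sub("\\*$", "", seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  guard <- if (!is.null(signal)) signal$end + rules$signal_buffer else 0L
  sites <- list()
  runs <- basic_runs(aa)
  for (r in runs) {
    pos <- r[2] # 0-based cleavage position = 1-based index of the run end
    if (r[1] < guard + 1L) next # run starts inside signal/buffer (1-based)
    if (pos <= guard) next
    if (rules$block_proline && pos < n && aa[pos + 1L] == "P") next
    run_len <- r[2] - r[1] + 1L
    motif <- paste(aa[r[1]:r[2]], collapse = "")
    cleave <- if (run_len == 1L) {
      motif == "R" && rules$monobasic_r &&
        any(vapply(rules$monobasic_offsets, function(off) {
          i <- pos - off # 0-based -> index pos-off+1 in 1-based
          i >= 0L && aa[i + 1L] %in% c("K", "R")
        }, logical(1)))
    } else if (run_len == 2L) {
      motif %in% rules$dibasic || (rules$cleave_kk && motif == "KK")
    } else TRUE
    if (!cleave) next
    kind <- if (run_len == 1L) "monobasic"
            else if (run_len == 2L) "dibasic" else "tetrabasic"
    sites[[length(sites) + 1L]] <- cleavage_site(pos, kind, motif, run_len)
  }
  if (!length(sites) || sites[[length(sites)]]$position < n)
    sites[[length(sites) + 1L]] <- cleavage_site(n, "terminus", "", 0L)
  sites
}

cleavage_site <- function(position, kind, motif, basic_run) {
  structure(list(position = as.integer(position), kind = kind,
                 motif = motif, basic_run = as.integer(basic_run)),
            class = "cleavage_site")
}

# maximal runs of K/R as (start, end) 1-based inclusive index pairs
basic_runs <- function(aa) {
  basic <- aa %in% c("K", "R")
  if (!any(basic)) return(list())
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}
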