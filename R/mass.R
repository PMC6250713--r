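# Monoisotopic peptide masses and b/y fragment ladders (MALDI regime,
# singly protonated ions only).

#' Modification state of a mature peptide
#'
#' @param amidated C-terminal amide (-0.984016 Da vs free acid).
#' @param pyroglutamate N-terminal pyroglutamate from Gln (-17.026549 Da).
#' @param sulfation_count Number of tyrosine O-sulfations (+79.956815 Da
#'   each).
#' @param c_term_truncation Number of C-terminal residues removed before
#'   C-terminal modifications are applied.
#' @return A list of class `modification_state`.
#' @export
modification_state <- function(amidated = FALSE, pyroglutamate = FALSE,
                               sulfation_count = 0L,
                               c_term_truncation = 0L) {
  stopifnot(sulfation_count >= 0L, c_term_truncation >= 0L)
  structure(list(amidated = amidated, pyroglutamate = pyroglutamate,
                 sulfation_count = as.integer(sulfation_count),
                 c_term_truncation = as.integer(c_term_truncation)),
            class = "modification_state")
}

residue_masses <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- unname(AA_MONO[aa])
  if (anyNA(m)) {
    pos <- which(is.na(m))[1]
    stop("nonstandard residue '", aa[pos], "' at position ", pos)
  }
  m
}

apply_truncation <- function(seq, mods) {
  k <- mods$c_term_truncation
  if (k >= nchar(seq))
    stop("truncation (", k, ") must be shorter than the peptide")
  if (k > 0L) substr(seq, 1L, nchar(seq) - k) else seq
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' The mass is the residue sum plus one water, with modification deltas:
#' amidation -0.984016, pyroglutamate (from Gln) -17.026549, sulfation
#' +79.956815 per site. C-terminal truncation removes trailing residues
#' before the C-terminal modifications are applied.
#'
#' @param seq Amino-acid string over the standard residues.
#' @param mods A [modification_state()].
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(seq, mods = modification_state()) {
  if (!nzchar(seq)) stop("empty peptide")
  seq <- apply_truncation(seq, mods)
  if (mods$pyroglutamate && !startsWith(seq, "Q") &&
      !startsWith(seq, "E"))
    stop("pyroglutamate requires an N-terminal Q (or E)")
  if (mods$sulfation_count >
      lengths(regmatches(seq, gregexpr("Y", seq, fixed = TRUE))))
    stop("sulfation_count exceeds the number of Y residues")
  mass <- sum(residue_masses(seq)) + WATER_MONO
  if (mods$amidated) mass <- mass + AMIDE_DELTA
  if (mods$pyroglutamate) mass <- mass + PYROGLU_DELTA
  mass + mods$sulfation_count * SULFO_DELTA
}

#' Singly protonated m/z of a peptide
#'
#' @inheritParams peptide_mass
#' @return `peptide_mass(seq, mods) + 1.007276`.
#' @export
peptide_mz <- function(seq, mods = modification_state()) {
  peptide_mass(seq, mods) + PROTON_MASS
}

#' b- and y-ion fragment ladders (1+)
#'
#' `b_i` is the sum of the first i residue masses plus a proton; `y_j` is
#' the sum of the last j residue masses plus water plus a proton.
#' N-terminal modifications (pyroglutamate) shift the b series, C-terminal
#' modifications (amidation, after truncation) shift the y series, so the
#' complementarity identity `b_i + y_(n-i) - 2 x proton = neutral mass`
#' holds for modified peptides too. Sulfation is not localized to a
#' residue and is left off the ladders.
#'
#' @param seq Amino-acid string, at least 2 residues after truncation.
#' @param mods A [modification_state()].
#' @return A list with numeric vectors `b` and `y` (lengths n-1).
#' @export
fragment_ladder <- function(seq, mods = modification_state()) {
  seq <- apply_truncation(seq, mods)
  n <- nchar(seq)
  if (n < 2L) stop("fragment ladder needs at least 2 residues")
  m <- residue_masses(seq)
  b <- cumsum(m)[-n] + PROTON_MASS
  y <- cumsum(rev(m))[-n] + WATER_MONO + PROTON_MASS # y[j] = last j residues
  if (mods$pyroglutamate) b <- b + PYROGLU_DELTA
  if (mods$amidated) y <- y + AMIDE_DELTA
  list(b = b, y = y)
}
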