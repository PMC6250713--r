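# Six-frame translation with coordinate bookkeeping.
#
# Coordinates are 0-based, half-open, always on the forward strand of the
# source transcript; reverse-frame records store the forward coordinates of
# the spanned interval. Codons containing an ambiguity (N) translate to X
# and are never treated as stops.

translate_codons <- function(nt, table) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(table[codons])
  aa[is.na(aa)] <- "X" # any codon containing N (or other ambiguity)
  paste(aa, collapse = "")
}

get_codon_table <- function(table = "1") {
  if (is.character(table) && length(table) == 1L)
    Biostrings::getGeneticCode(table)
  else table
}

#' Translate a transcript in all six reading frames
#'
#' Frames +1..+3 read the forward strand, -1..-3 the reverse complement.
#' Every returned record carries an `origin` mapping each amino acid back to
#' its codon on the forward strand of the source transcript.
#'
#' @param t A [transcript_record()].
#' @param table Codon table: an NCBI genetic-code name or id accepted by
#'   `Biostrings::getGeneticCode()` (default the standard code), or a named
#'   codon-to-residue character vector.
#' @return A list of six protein records named `"+1"`, `"+2"`, `"+3"`,
#'   `"-1"`, `"-2"`, `"-3"`. Frame translations may contain internal `*`
#'   stop characters.
#' @export
six_frame_translate <- function(t, table = "1") {
  stopifnot(inherits(t, "transcript_record"))
  L <- nchar(t$seq)
  if (L < 3L) stop("transcript '", t$id, "' is shorter than one codon")
  tab <- get_codon_table(table)
  rc <- revcomp(t$seq)
  out <- vector("list", 6L)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (k in seq_along(frames)) {
    f <- frames[k]
    off <- abs(f) - 1L
    s <- if (f > 0L) t$seq else rc
    naa <- (L - off) %/% 3L
    aa <- translate_codons(substr(s, off + 1L, off + 3L * naa), tab)
    span <- if (f > 0L) c(off, off + 3L * naa)
            else c(L - off - 3L * naa, L - off)
    rec <- structure(list(
      id = paste0(t$id, "|frame", sprintf("%+d", f)),
      seq = aa, description = "",
      origin = list(transcript = t$id, frame = f,
                    start = span[1], end = span[2])),
      class = "protein_record")
    out[[k]] <- rec
  }
  names(out) <- sprintf("%+d", frames)
  out
}

# forward-strand codon coordinates (0-based half-open) of aa position i
# (0-based) in a frame translation
codon_coords <- function(origin, i, transcript_length) {
  off <- abs(origin$frame) - 1L
  if (origin$frame > 0L) c(off + 3L * i, off + 3L * i + 3L)
  else c(transcript_length - off - 3L * i - 3L,
         transcript_length - off - 3L * i)
}
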