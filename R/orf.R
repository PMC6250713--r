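# Open-reading-frame extraction across all six frames.

#' Find open reading frames in a transcript
#'
#' Reports all maximal (stop-to-stop) ORFs of at least `min_aa` residues in
#' all six frames. When a maximal segment does not itself begin with Met but
#' contains one, the Met-initiated sub-ORF is reported as an additional
#' call. `has_start`/`has_stop` flag partiality: a segment that runs off the
#' transcript end without a stop codon has `has_stop = FALSE`, one that
#' starts at the transcript edge without an upstream stop and without Met
#' has `has_start = FALSE`.
#'
#' @param t A [transcript_record()].
#' @param min_aa Minimum protein length in residues (>= 1).
#' @param table Codon table passed to [six_frame_translate()].
#' @return A list of `orf_call` objects sorted by decreasing protein length,
#'   ties broken by (transcript id, frame, start). Each call has fields
#'   `transcript`, `frame`, `start`, `end` (0-based half-open forward-strand
#'   nucleotide coordinates, including the stop codon when present),
#'   `protein` (a protein record, no stop character), `has_start`,
#'   `has_stop`.
#' @export
find_orfs <- function(t, min_aa = 30L, table = "1") {
  stopifnot(min_aa >= 1L)
  L <- nchar(t$seq)
  frames <- six_frame_translate(t, table)
  calls <- list()
  for (fp in frames) {
    aa <- strsplit(fp$seq, "", fixed = TRUE)[[1]]
    if (length(aa) == 0L) next
    stops <- which(aa == "*")
    seg_start <- c(1L, stops + 1L)
    seg_end <- c(stops - 1L, length(aa)) # inclusive aa indices
    for (s in seq_along(seg_start)) {
      a0 <- seg_start[s]; a1 <- seg_end[s]
      if (a1 < a0) next
      stop_follows <- s <= length(stops)
      seg <- paste(aa[a0:a1], collapse = "")
      starts_met <- aa[a0] == "M"
      cand <- list(c(a0, starts_met))
      if (!starts_met) {
        met <- which(aa[a0:a1] == "M")
        if (length(met)) cand <- c(cand, list(c(a0 + met[1] - 1L, TRUE)))
      }
      for (cc in cand) {
        b0 <- cc[1]
        prot <- paste(aa[b0:a1], collapse = "")
        if (nchar(prot) < min_aa) next
        calls[[length(calls) + 1L]] <- make_orf_call(
          t, fp$origin, b0 - 1L, a1, stop_follows, as.logical(cc[2]), prot, L)
      }
    }
  }
  ord <- order(-vapply(calls, function(x) nchar(x$protein$seq), numeric(1)),
               vapply(calls, function(x) x$transcript, character(1)),
               vapply(calls, function(x) x$frame, integer(1)),
               vapply(calls, function(x) x$start, integer(1)))
  calls[ord]
}

# aa0: 0-based aa index of first residue; aa_last: 1-based index of last
make_orf_call <- function(t, origin, aa0, aa_last, has_stop, has_start,
                          prot, L) {
  c1 <- codon_coords(origin, aa0, L)
  c2 <- codon_coords(origin, aa_last - 1L + if (has_stop) 1L else 0L, L)
  start <- min(c1, c2); end <- max(c1, c2)
  pid <- paste0(t$id, "|", sprintf("%+d", origin$frame), "|", start)
  structure(list(
    transcript = t$id, frame = origin$frame,
    start = as.integer(start), end = as.integer(end),
    protein = structure(list(id = pid, seq = prot, description = "",
                             origin = list(transcript = t$id,
                                           frame = origin$frame,
                                           start = as.integer(start),
                                           end = as.integer(end))),
                        class = "protein_record"),
    has_start = has_start, has_stop = has_stop),
    class = "orf_call")
}

#' @export
print.orf_call <- function(x, ...) {
  cat("<ORF ", x$transcript, " frame ", sprintf("%+d", x$frame), " [",
      x$start, ",", x$end, ") ", nchar(x$protein$seq), " aa",
      if (!x$has_start) " partial-5'", if (!x$has_stop) " partial-3'",
      "\n", sep = "")
  invisible(x)
}

#' Tabulate ORF calls
#'
#' @param orfs List of `orf_call` objects from [find_orfs()].
#' @return A data frame with one row per call.
#' @export
orf_table <- function(orfs) {
  data.frame(
    transcript = vapply(orfs, `[[`, character(1), "transcript"),
    frame = vapply(orfs, `[[`, integer(1), "frame"),
    start = vapply(orfs, `[[`, integer(1), "start"),
    end = vapply(orfs, `[[`, integer(1), "end"),
    length_aa = vapply(orfs, function(x) nchar(x$protein$seq), integer(1)),
    has_start = vapply(orfs, `[[`, logical(1), "has_start"),
    has_stop = vapply(orfs, `[[`, logical(1), "has_stop"),
    protein = vapply(orfs, function(x) x$protein$seq, character(1)),
    stringsAsFactors = FALSE)
}

#' Export ORF calls as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive convention of GFF3.
#'
#' @param orfs List of `orf_call` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, path) {
  lines <- c("##gff-version 3", vapply(orfs, function(x) {
    paste(x$transcript, "npmine", "ORF", x$start + 1L, x$end,
          ".", if (x$frame > 0) "+" else "-", "0",
          paste0("ID=", x$protein$id, ";has_start=",
                 tolower(x$has_start), ";has_stop=", tolower(x$has_stop)),
          sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
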