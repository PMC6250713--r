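# Deriving mature peptides from cleavage sites, and the full precursor
# annotation pipeline (signal -> sites -> peptides).

#' Derive mature peptides from predicted cleavage sites
#'
#' Segments between consecutive sites are emitted in N-to-C order. The
#' basic run of each non-terminal site is trimmed from its upstream
#' segment; a trimmed segment ending in glycine donates that G to
#' C-terminal amidation (`amidated = TRUE`, the G is consumed); a peptide
#' beginning with Gln is flagged `pyroglutamate` (both modified and
#' unmodified forms are considered downstream during mass matching).
#' Zero-length segments are dropped; peptides shorter than
#' `rules$fragment_min` are retained but flagged `fragment`.
#'
#' @param p A [protein_record()] or amino-acid string.
#' @param signal Optional signal span (its residues are excluded).
#' @param sites Cleavage sites from [predict_cleavage_sites()], sorted.
#' @param rules A [rule_config()].
#' @return List of `mature_peptide` objects with fields `seq`, `start`,
#'   `end` (0-based half-open in the precursor, excluding trimmed basics
#'   and the consumed G), `amidated`, `pyroglutamate`, `fragment`,
#'   `copy_index`, `precursor`.
#' @export
derive_peptides <- function(p, signal = NULL, sites = NULL,
                            rules = rule_config()) {
  seq <- if (inherits(p, "protein_record")) p$seq else p
  pid <- if (inherits(p, "protein_record")) p$id else "precursor"
  seq <- sub("\\*$", "", seq)
  if (is.null(sites)) sites <- predict_cleavage_sites(seq, signal, rules)
  pos <- vapply(sites, `[[`, integer(1), "position")
  if (is.unsorted(pos, strictly = TRUE))
    stop("cleavage sites must be strictly increasing")
  cursor <- if (!is.null(signal)) signal$end else 0L
  peptides <- list()
  for (s in sites) {
    if (s$position <= cursor) { cursor <- s$position; next }
    raw_start <- cursor
    raw_end <- s$position
    pep_end <- raw_end - s$basic_run
    cursor <- s$position
    if (pep_end <= raw_start) next
    amidated <- FALSE
    if (s$kind != "terminus" &&
        substr(seq, pep_end, pep_end) == "G" && pep_end - 1L > raw_start) {
      amidated <- TRUE
      pep_end <- pep_end - 1L
    }
    pseq <- substr(seq, raw_start + 1L, pep_end)
    first <- substr(pseq, 1L, 1L)
    pyro <- first == "Q" || (rules$pyroglu_from_e && first == "E")
    peptides[[length(peptides) + 1L]] <- structure(list(
      seq = pseq, start = raw_start, end = pep_end,
      amidated = amidated, pyroglutamate = pyro,
      fragment = nchar(pseq) < rules$fragment_min,
      copy_index = length(peptides) + 1L, precursor = pid),
      class = "mature_peptide")
  }
  peptides
}

#' Annotate a candidate precursor
#'
#' Runs the full structural annotation: signal-peptide prediction,
#' convertase cleavage-site prediction, and mature-peptide derivation, with
#' completeness flags. Deterministic.
#'
#' @param p A [protein_record()] or amino-acid string. A trailing `*`
#'   (stop) marks the C-terminus as complete.
#' @param rules A [rule_config()].
#' @param signal Optional externally supplied signal span (overrides the
#'   heuristic), a list with `start`, `end`.
#' @param complete_c_terminus Whether the source ORF had a stop codon;
#'   defaults to `TRUE`, or to the presence of a trailing `*` on the
#'   sequence.
#' @param family Optional family label.
#' @return An object of class `precursor_model`: fields `protein`,
#'   `signal`, `sites`, `peptides`, `flags` (list with
#'   `complete_n_terminus`, `complete_c_terminus`), `family`.
#' @export
annotate_precursor <- function(p, rules = rule_config(), signal = NULL,
                               complete_c_terminus = NULL, family = NULL) {
  if (!inherits(p, "protein_record"))
    p <- protein_record("precursor", p)
  if (is.null(complete_c_terminus))
    complete_c_terminus <- endsWith(p$seq, "*")
  body <- sub("\\*$", "", p$seq)
  if (is.null(signal)) signal <- predict_signal_peptide(body)
  sites <- predict_cleavage_sites(body, signal, rules)
  peptides <- derive_peptides(p, signal, sites, rules)
  structure(list(
    protein = p, signal = signal, sites = sites, peptides = peptides,
    flags = list(complete_n_terminus = !is.null(signal),
                 complete_c_terminus = isTRUE(complete_c_terminus)),
    family = family),
    class = "precursor_model")
}

#' Reconstruct the precursor sequence from its annotation
#'
#' Concatenates signal peptide, mature peptides, consumed amidation
#' glycines and trimmed basic residues in order. Equality with the input
#' protein is the sequence-conservation invariant of the annotation.
#'
#' @param m A `precursor_model`.
#' @return The reconstructed amino-acid string.
#' @export
reconstruct_precursor <- function(m) {
  seq <- sub("\\*$", "", m$protein$seq)
  out <- if (!is.null(m$signal)) substr(seq, 1L, m$signal$end) else ""
  cursor <- if (!is.null(m$signal)) m$signal$end else 0L
  pi <- 1L
  for (s in m$sites) {
    if (s$position <= cursor) next
    if (pi <= length(m$peptides) && m$peptides[[pi]]$start >= cursor &&
        m$peptides[[pi]]$end <= s$position) {
      pep <- m$peptides[[pi]]
      pi <- pi + 1L
      out <- paste0(out, pep$seq, if (pep$amidated) "G" else "")
    }
    out <- paste0(out, s$motif)
    cursor <- s$position
  }
  out
}

#' @export
print.precursor_model <- function(x, ...) {
  n <- nchar(sub("\\*$", "", x$protein$seq))
  cat("<precursor ", x$protein$id, "> ", n, " aa",
      if (!is.null(x$family)) paste0(" [", x$family, "]"), "\n", sep = "")
  if (!is.null(x$signal))
    cat("  signal peptide: 1..", x$signal$end, "\n", sep = "")
  else cat("  signal peptide: none (N-terminally incomplete?)\n")
  np <- length(x$peptides)
  na <- sum(vapply(x$peptides, `[[`, logical(1), "amidated"))
  cat("  cleavage sites: ",
      sum(vapply(x$sites, function(s) s$kind != "terminus", logical(1))),
      "; mature peptides: ", np, " (", na, " amidated)\n", sep = "")
  invisible(x)
}

#' @method summary precursor_model
#' @export
summary.precursor_model <- function(object, ...) {
  print(object)
  for (pep in object$peptides) {
    mods <- c(if (pep$pyroglutamate) "pQ", if (pep$amidated) "amide",
              if (pep$fragment) "fragment")
    cat(sprintf("  %2d. %s%s\n", pep$copy_index, pep$seq,
                if (length(mods)) paste0(" [", paste(mods, collapse = ","),
                                         "]") else ""))
  }
  invisible(object)
}

#' Tabulate the mature peptides of one or more precursor models
#'
#' @param models A `precursor_model` or list of them.
#' @return A data frame: precursor, family, copy_index, seq, start, end,
#'   amidated, pyroglutamate, fragment.
#' @export
peptide_table <- function(models) {
  if (inherits(models, "precursor_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    if (!length(m$peptides)) return(NULL)
    do.call(rbind, lapply(m$peptides, function(p) data.frame(
      precursor = p$precursor, family = m$family %||% NA_character_,
      copy_index = p$copy_index, seq = p$seq, start = p$start, end = p$end,
      amidated = p$amidated, pyroglutamate = p$pyroglutamate,
      fragment = p$fragment, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(precursor = character(), family = character(),
                      copy_index = integer(), seq = character(),
                      start = integer(), end = integer(),
                      amidated = logical(), pyroglutamate = logical(),
                      fragment = logical(), stringsAsFactors = FALSE)
  out
}

#' Export precursor features (signal, peptides) as GFF3
#'
#' @param models A `precursor_model` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_precursor_gff3 <- function(models, path) {
  if (inherits(models, "precursor_model")) models <- list(models)
  lines <- "##gff-version 3"
  for (m in models) {
    id <- m$protein$id
    if (!is.null(m$signal))
      lines <- c(lines, paste(id, "npmine", "signal_peptide", 1L,
                              m$signal$end, ".", "+", ".",
                              paste0("ID=", id, ":signal"), sep = "\t"))
    for (p in m$peptides)
      lines <- c(lines, paste(
        id, "npmine", "mature_peptide", p$start + 1L, p$end, ".", "+", ".",
        paste0("ID=", id, ":pep", p$copy_index,
               ";amidated=", tolower(p$amidated),
               ";pyroglutamate=", tolower(p$pyroglutamate)), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
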