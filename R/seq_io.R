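# Sequence records and FASTA input/output.
#
# Records are lightweight S3 lists. A dataset is an unnamed list of records;
# ids are unique within a dataset (enforced on read and on construction
# helpers that take several records).

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(AA_STANDARD, "X", "*")

#' Create a transcript (nucleotide) record
#'
#' @param id Non-empty identifier.
#' @param seq Nucleotide sequence over `A,C,G,T,N` (lowercase is normalized).
#' @param description Optional free-text description.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, seq, description = "") {
  seq <- toupper(seq)
  check_id(id)
  check_alphabet(seq, NT_ALPHABET, id)
  if (nchar(seq) < 1L) stop("sequence of '", id, "' is empty")
  structure(list(id = id, seq = seq, description = description),
            class = "transcript_record")
}

#' Create a protein (amino-acid) record
#'
#' @param id Non-empty identifier.
#' @param seq Amino-acid sequence over the 20 standard residues plus `X` and
#'   a single optional trailing `*`.
#' @param description Optional description.
#' @param origin Optional provenance: a list with `transcript`, `frame`
#'   (one of 1,2,3,-1,-2,-3), `start`, `end` (0-based half-open nucleotide
#'   coordinates on the forward strand of the source transcript).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, seq, description = "", origin = NULL) {
  seq <- toupper(seq)
  check_id(id)
  body <- sub("\\*$", "", seq)
  check_alphabet(body, setdiff(AA_ALPHABET, "*"), id)
  if (grepl("*", body, fixed = TRUE))
    stop("record '", id, "' has an internal stop character")
  if (nchar(seq) < 1L) stop("sequence of '", id, "' is empty")
  if (!is.null(origin)) {
    stopifnot(origin$frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    span <- origin$end - origin$start
    naa <- nchar(body)
    if (span < 3L * naa || span > 3L * naa + 3L)
      stop("origin span of '", id, "' inconsistent with protein length")
  }
  structure(list(id = id, seq = seq, description = description,
                 origin = origin),
            class = "protein_record")
}

check_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
}

check_alphabet <- function(seq, alphabet, id) {
  ok <- strsplit(seq, "", fixed = TRUE)[[1]] %in% alphabet
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop("illegal character '", substr(seq, pos, pos), "' in record '", id,
         "' at position ", pos)
  }
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` for nucleotide records, `"aa"` for protein records.
#' @return A list of [transcript_record()] or [protein_record()] objects, in
#'   file order. Duplicate ids or illegal characters are errors.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- ifelse(grepl("\\s", names(set)),
                 sub("^\\S+\\s+", "", names(set)), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate record id '", dup, "' in ", path)
  }
  seqs <- as.character(set)
  ctor <- if (alphabet == "nt") transcript_record else protein_record
  unname(Map(function(i, s, d) ctor(i, s, d), ids, seqs, desc))
}

#' Write records to a FASTA file
#'
#' @param records List of transcript or protein records.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description %||% ""))
      paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$seq
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Nucleotide string (may contain `N`).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

record_ids <- function(records) vapply(records, `[[`, character(1), "id")

#' @export
print.transcript_record <- function(x, ...) {
  cat("<transcript ", x$id, "> ", nchar(x$seq), " nt\n", sep = "")
  invisible(x)
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein ", x$id, "> ", nchar(sub("\\*$", "", x$seq)), " aa",
      if (!is.null(x$origin))
        paste0(" [", x$origin$transcript, " frame ",
               sprintf("%+d", x$origin$frame), "]"),
      "\n", sep = "")
  invisible(x)
}
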