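# Restricted-pattern motifs for neuropeptide families, paracopy censuses
# and family classification.
#
# The pattern language covers what family definitions need and nothing
# more: literal residues, X (or x) for any residue, character classes
# [ABC], and bounded repeats {m} / {m,n} attached to any of those.
# Unbounded repeats are deliberately not supported, so matching is a
# single deterministic pass.

#' Compile a family motif
#'
#' @param pattern Pattern string, e.g. `"W x{6} W"`, `"FXXWG"`,
#'   `"PR[LIVM]"`. Whitespace is ignored.
#' @param name Motif name.
#' @param family Family label the motif diagnoses.
#' @param anchor One of `"c_terminal"` (match must end at the peptide's
#'   C-terminus), `"n_terminal"`, `"both"`, or `"none"`.
#' @param requires_amide When `TRUE` the motif only matches amidated
#'   peptides.
#' @param note Free-text metadata.
#' @return An object of class `motif_spec`.
#' @export
compile_motif <- function(pattern, name = pattern, family = name,
                          anchor = c("c_terminal", "n_terminal", "both",
                                     "none"),
                          requires_amide = FALSE, note = "") {
  anchor <- match.arg(anchor)
  regex <- motif_to_regex(pattern)
  if (anchor %in% c("n_terminal", "both")) regex <- paste0("^", regex)
  if (anchor %in% c("c_terminal", "both")) regex <- paste0(regex, "$")
  structure(list(name = name, family = family, pattern = pattern,
                 anchor = anchor, requires_amide = requires_amide,
                 regex = regex, note = note),
            class = "motif_spec")
}

motif_to_regex <- function(pattern) {
  src <- gsub("\\s+", "", pattern)
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  units <- character(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("motif parse error at position ", i,
                      ": unclosed '['")
      if (j == i + 1L) stop("motif parse error at position ", i,
                            ": empty class")
      for (k in (i + 1L):(j - 1L))
        if (!chars[k] %in% AA_STANDARD)
          stop("motif parse error at position ", k,
               ": '", chars[k], "' is not a residue")
      unit <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch %in% c("X", "x")) {
      unit <- "."
      i <- i + 1L
    } else if (ch %in% AA_STANDARD) {
      unit <- ch
      i <- i + 1L
    } else {
      stop("motif parse error at position ", i, ": unexpected '", ch, "'")
    }
    if (i <= n && chars[i] == "{") {
      j <- i + 1L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n) stop("motif parse error at position ", i,
                      ": unclosed '{'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body))
        stop("motif parse error at position ", i + 1L,
             ": repeat must be {m} or {m,n}")
      unit <- paste0(unit, "{", body, "}")
      i <- j + 1L
    }
    units <- c(units, unit)
  }
  if (!length(units)) stop("motif parse error: empty pattern")
  paste(units, collapse = "")
}

#' Does a motif match a mature peptide?
#'
#' @param spec A `motif_spec` from [compile_motif()].
#' @param peptide A `mature_peptide` (or a plain string, in which case the
#'   peptide is treated as amidated only if `amidated` says so).
#' @param amidated Amidation state when `peptide` is a plain string.
#' @return Logical.
#' @export
motif_matches <- function(spec, peptide, amidated = FALSE) {
  if (inherits(peptide, "mature_peptide")) {
    amidated <- peptide$amidated
    peptide <- peptide$seq
  }
  if (spec$requires_amide && !amidated) return(FALSE)
  grepl(spec$regex, peptide, perl = TRUE)
}

#' Count motif paracopies in an annotated precursor
#'
#' @param m A `precursor_model`.
#' @param spec A `motif_spec`.
#' @return A one-row data frame: precursor, motif, family, count, and the
#'   comma-separated copy indices matched.
#' @export
count_paracopies <- function(m, spec) {
  hit <- vapply(m$peptides, function(p) motif_matches(spec, p), logical(1))
  idx <- vapply(m$peptides[hit], `[[`, integer(1), "copy_index")
  data.frame(precursor = m$protein$id, motif = spec$name,
             family = spec$family, count = sum(hit),
             copies = paste(idx, collapse = ","), stringsAsFactors = FALSE)
}

#' The default neuropeptide-family motif library
#'
#' Encodes the core-peptide motifs used for family assignment: the MIP
#' W(6x)W-amide and the heteropteran W(7x)W-amide variant, kinin
#' FXXWG-amide and the FSXWA-amide variant, FMRF-amide and the infrequent
#' FIRF-amide, sulfakinin GHMRF-amide and the unusual GYMRF-amide,
#' FGL-amide allatostatin and its LGL-amide variant, the amidated ETH
#' PR[LIVM] core, RY-amide (with the provisional FYX(3)RY-amide form, see
#' its note), myosuppressin FLRF-amide, and the AKH signature (pyroGlu
#' start, Trp at position 8, total length 8-10).
#'
#' @return A list of `motif_spec` objects.
#' @export
default_motif_library <- function() {
  list(
    compile_motif("W x{6} W", "MIP-W6W", "MIP", "c_terminal", TRUE,
                  "canonical myoinhibitory peptide core"),
    compile_motif("W x{7} W", "MIP-W7W", "MIP", "c_terminal", TRUE,
                  "heteropteran W(7x)W variant"),
    compile_motif("F X X W G", "kinin-FXXWG", "kinin", "c_terminal", TRUE,
                  "conserved insect kinin C-terminus"),
    compile_motif("F S X W A", "kinin-FSXWA", "kinin", "c_terminal", TRUE,
                  "heteropteran kinin variant"),
    compile_motif("F M R F", "FMRFamide", "FMRFamide", "c_terminal", TRUE,
                  "canonical FMRFamide"),
    compile_motif("F I R F", "FIRFamide", "FMRFamide", "c_terminal", TRUE,
                  "infrequent heteropteran FIRF variant"),
    compile_motif("G H M R F", "SK-GHMRF", "sulfakinin", "c_terminal", TRUE,
                  "frequent sulfakinin core"),
    compile_motif("G Y M R F", "SK-GYMRF", "sulfakinin", "c_terminal", TRUE,
                  "unusual sulfakinin core"),
    compile_motif("F G L", "FGLamide", "FGL-AST", "c_terminal", TRUE,
                  "FGLamide allatostatin"),
    compile_motif("L G L", "LGLamide", "FGL-AST", "c_terminal", TRUE,
                  "unusual first-paracopy LGLamide variant"),
    compile_motif("P R [LIVM]", "ETH-core", "ETH", "c_terminal", TRUE,
                  "ecdysis-triggering hormone core"),
    compile_motif("R Y", "RYamide", "RYamide", "c_terminal", TRUE,
                  "RYamide C-terminus"),
    compile_motif("F Y x{3} R Y", "RYa-FY3RY", "RYamide", "c_terminal",
                  TRUE,
                  paste("provisional encoding of the ambiguous FY3(X)RY",
                        "notation as F Y x{3} R Y")),
    compile_motif("F L R F", "MS-FLRF", "myosuppressin", "c_terminal", TRUE,
                  "pentatomid myosuppressin C-terminus"),
    compile_motif("Q x{6} W x{0,2}", "AKH-core", "AKH", "both", TRUE,
                  "pyroGlu start, W at position 8, length 8-10"))
}

#' Rank candidate family labels for a precursor
#'
#' Families are ranked by matched paracopy count (summed over the family's
#' motifs, each peptide counted at most once per family), with an optional
#' homology score as secondary key. Ties share a rank and are reported,
#' not broken silently.
#'
#' @param m A `precursor_model`.
#' @param library List of `motif_spec`s (default
#'   [default_motif_library()]).
#' @param homology_scores Optional named numeric vector of per-family
#'   alignment scores used as a secondary ranking key.
#' @return A data frame (possibly empty): family, paracopies, score, rank.
#' @export
classify_family <- function(m, library = default_motif_library(),
                            homology_scores = NULL) {
  if (!length(library)) stop("motif library is empty")
  fams <- unique(vapply(library, `[[`, character(1), "family"))
  counts <- vapply(fams, function(fam) {
    specs <- Filter(function(s) s$family == fam, library)
    matched <- rep(FALSE, length(m$peptides))
    for (spec in specs)
      matched <- matched | vapply(m$peptides, function(p)
        motif_matches(spec, p), logical(1))
    sum(matched)
  }, integer(1))
  keep <- counts > 0L
  if (!any(keep))
    return(data.frame(family = character(), paracopies = integer(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  fams <- fams[keep]; counts <- counts[keep]
  score <- if (!is.null(homology_scores))
    unname(homology_scores[fams]) else rep(NA_real_, length(fams))
  score[is.na(score)] <- -Inf
  ord <- order(-counts, -score, fams)
  fams <- fams[ord]; counts <- counts[ord]; score <- score[ord]
  key <- paste(counts, score)
  rank <- match(key, unique(key))
  data.frame(family = fams, paracopies = counts,
             score = ifelse(is.infinite(score), NA_real_, score),
             rank = rank, stringsAsFactors = FALSE)
}

#' Run a motif census over several precursor models
#'
#' @param models List of `precursor_model`s.
#' @param library List of `motif_spec`s.
#' @return A data frame of [count_paracopies()] rows (all combinations).
#' @export
motif_census <- function(models, library = default_motif_library()) {
  if (inherits(models, "precursor_model")) models <- list(models)
  rows <- lapply(models, function(m)
    do.call(rbind, lapply(library, function(spec)
      count_paracopies(m, spec))))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(precursor = character(), motif = character(),
                      family = character(), count = integer(),
                      copies = character(), stringsAsFactors = FALSE)
  out
}
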