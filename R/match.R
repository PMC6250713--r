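# Matching observed MALDI-TOF(/TOF) masses against predicted mature
# peptides expanded over a variable-modification space.

#' Match observed masses to a peptide library
#'
#' Each library peptide is expanded over the enabled modification space:
#' amidation as annotated (plus, optionally, the free-acid form),
#' pyroglutamate in both states when the peptide starts with Q, C-terminal
#' truncation 0..`truncation_max`, and 0..nY sulfations. Every candidate
#' whose singly protonated m/z lies within `tol_ppm` of an observation is
#' reported; matches are ranked per observation by (fragment ions matched,
#' then absolute ppm error). Deterministic.
#'
#' @param obs A data frame with columns `mz` (numeric), optional `charge`
#'   (only 1 is modeled) and optional `fragments` (semicolon-separated
#'   fragment m/z strings), e.g. from [read_observations()].
#' @param library A list of `mature_peptide` objects, or a peptide table
#'   (data frame with `seq`, `amidated`, `pyroglutamate`, `precursor`).
#' @param tol_ppm Precursor tolerance in ppm (default 50, MALDI-TOF
#'   regime).
#' @param frag_tol_da Fragment tolerance in Da (default 0.3, TOF/TOF
#'   regime).
#' @param mod_space List of switches: `truncation_max` (default 1),
#'   `sulfation` (default TRUE), `pyroglu_both` (default TRUE: N-terminal
#'   Q peptides are searched with and without pyroGlu), `amide_both`
#'   (default FALSE: amidation is taken from the annotation only).
#' @return A data frame, one row per (observation, candidate) match:
#'   `obs_index`, `obs_mz`, `peptide`, `precursor`, `seq`, `amidated`,
#'   `pyroglutamate`, `sulfation_count`, `c_term_truncation`, `mz`,
#'   `ppm`, `frag_matched`, `frag_total`, `rank`.
#' @export
match_observations <- function(obs, library, tol_ppm = 50,
                               frag_tol_da = 0.3, mod_space = list()) {
  stopifnot(tol_ppm > 0, frag_tol_da > 0)
  ms <- utils::modifyList(list(truncation_max = 1L, sulfation = TRUE,
                               pyroglu_both = TRUE, amide_both = FALSE),
                          mod_space)
  cand <- expand_mod_space(library, ms)
  if (!nrow(obs %||% data.frame())) return(empty_matches())
  rows <- list()
  for (oi in seq_len(nrow(obs))) {
    mz_obs <- obs$mz[oi]
    frags <- parse_fragments(obs$fragments[oi] %||% NA_character_)
    ppm <- (cand$mz - mz_obs) / mz_obs * 1e6
    sel <- which(abs(ppm) <= tol_ppm)
    if (!length(sel)) next
    sub <- cand[sel, , drop = FALSE]
    sub$obs_index <- oi
    sub$obs_mz <- mz_obs
    sub$ppm <- ppm[sel]
    fm <- t(vapply(seq_len(nrow(sub)), function(k) {
      count_fragment_matches(sub$seq[k], sub[k, ], frags, frag_tol_da)
    }, numeric(2)))
    sub$frag_matched <- as.integer(fm[, 1])
    sub$frag_total <- as.integer(fm[, 2])
    ord <- order(-sub$frag_matched, abs(sub$ppm), sub$peptide)
    sub <- sub[ord, , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    rows[[length(rows) + 1L]] <- sub
  }
  if (!length(rows)) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("obs_index", "obs_mz", "peptide", "precursor", "seq", "amidated",
          "pyroglutamate", "sulfation_count", "c_term_truncation", "mz",
          "ppm", "frag_matched", "frag_total", "rank")]
}

empty_matches <- function() {
  data.frame(obs_index = integer(), obs_mz = numeric(), peptide = character(),
             precursor = character(), seq = character(), amidated = logical(),
             pyroglutamate = logical(), sulfation_count = integer(),
             c_term_truncation = integer(), mz = numeric(), ppm = numeric(),
             frag_matched = integer(), frag_total = integer(),
             rank = integer(), stringsAsFactors = FALSE)
}

library_as_table <- function(library) {
  if (is.data.frame(library)) {
    library$peptide <- library$peptide %||%
      paste0(library$precursor, ":", seq_len(nrow(library)))
    return(library)
  }
  do.call(rbind, lapply(library, function(p) data.frame(
    peptide = paste0(p$precursor, ":", p$copy_index), precursor = p$precursor,
    seq = p$seq, amidated = p$amidated, pyroglutamate = p$pyroglutamate,
    stringsAsFactors = FALSE)))
}

# one row per (peptide, modification state) with its theoretical 1+ m/z
expand_mod_space <- function(library, ms) {
  tab <- library_as_table(library)
  rows <- list()
  for (k in seq_len(nrow(tab))) {
    seq <- tab$seq[k]
    amide_states <- if (isTRUE(tab$amidated[k]))
      if (ms$amide_both) c(TRUE, FALSE) else TRUE else FALSE
    pyro_states <- if (startsWith(seq, "Q"))
      if (ms$pyroglu_both) c(FALSE, TRUE) else isTRUE(tab$pyroglutamate[k])
      else FALSE
    for (amide in amide_states)
      for (pyro in unique(pyro_states))
        for (trunc in 0:min(ms$truncation_max, nchar(seq) - 1L)) {
          body <- substr(seq, 1L, nchar(seq) - trunc)
          n_y <- if (ms$sulfation)
            nchar(gsub("[^Y]", "", body)) else 0L
          for (sulf in 0:n_y) {
            mods <- modification_state(amide, pyro, sulf, trunc)
            rows[[length(rows) + 1L]] <- data.frame(
              peptide = tab$peptide[k], precursor = tab$precursor[k],
              seq = seq, amidated = amide, pyroglutamate = pyro,
              sulfation_count = sulf, c_term_truncation = trunc,
              mz = peptide_mz(seq, mods), stringsAsFactors = FALSE)
          }
        }
  }
  do.call(rbind, rows)
}

parse_fragments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

count_fragment_matches <- function(seq, row, frags, tol) {
  if (!length(frags)) return(c(0, 0))
  mods <- modification_state(row$amidated, row$pyroglutamate,
                             row$sulfation_count, row$c_term_truncation)
  body <- substr(seq, 1L, nchar(seq) - row$c_term_truncation)
  if (nchar(body) < 2L) return(c(0, length(frags)))
  lad <- fragment_ladder(seq, mods)
  theo <- c(lad$b, lad$y)
  hit <- vapply(frags, function(f) any(abs(theo - f) <= tol), logical(1))
  c(sum(hit), length(frags))
}

#' Read an observation table (TSV)
#'
#' Expected columns: `mz`, optional `charge`, optional `fragments`
#' (semicolon-separated fragment m/z values).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data frame of observations.
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) stop("observation table needs an 'mz' column")
  df
}

#' Read observations from an MGF file
#'
#' Parses the BEGIN IONS / PEPMASS dialect; peak lines inside a block
#' become the observation's fragment list.
#'
#' @param path Path to an MGF file.
#' @return A data frame with `mz`, `charge`, `fragments`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  rows <- list(); cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      cur <- list(mz = NA_real_, charge = 1L, frags = numeric(0))
    } else if (ln == "END IONS") {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = cur$mz, charge = cur$charge,
        fragments = paste(cur$frags, collapse = ";"),
        stringsAsFactors = FALSE)
      cur <- NULL
    } else if (!is.null(cur)) {
      if (startsWith(ln, "PEPMASS=")) {
        cur$mz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                      "[ \t]")[[1]][1])
      } else if (startsWith(ln, "CHARGE=")) {
        cur$charge <- as.integer(gsub("[^0-9]", "", ln))
      } else if (grepl("^[0-9]", ln)) {
        cur$frags <- c(cur$frags,
                       as.numeric(strsplit(ln, "[ \t]+")[[1]][1]))
      }
    }
  }
  if (!length(rows))
    return(data.frame(mz = numeric(), charge = integer(),
                      fragments = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
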