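# Synthetic transcriptomes, precursor panels and MS observations with full
# ground truth.
#
# Blueprints describe precursor architectures (signal peptide, core-peptide
# motifs with amidation donors, spacers, dibasic flanks); instantiation is
# constrained so that the cleavage rule engine provably recovers the
# construction: random fill avoids K/R/G/C/W, internal arginines of core
# patterns sit at least 7 residues into their segment (so the monobasic
# -4/-6/-8 supports can never reach a flanking dibasic), and every
# instantiated precursor is verified against its own annotation before it
# is accepted (bounded retries).

FILL_AA <- setdiff(AA_STANDARD, c("K", "R", "G", "C", "W"))
SPACER_AA <- c("S", "N", "Q", "D", "E", "T", "A", "H", "P")

#' Blueprint of a precursor architecture
#'
#' @param family Family label.
#' @param peptides List of core-peptide specs, each a list with `pattern`
#'   (motif-language pattern, see [compile_motif()]) and `amidated`.
#' @param signal_len Signal-peptide length (>= 15).
#' @param spacer_prob Probability of a spacer segment between cores (and
#'   before the first when `leading_spacer` is `NA`).
#' @param spacer_len Length range of spacer segments.
#' @param leading_spacer,trailing_spacer Force (or forbid) spacers at the
#'   precursor ends; `leading_spacer = NA` draws with `spacer_prob`.
#' @return An object of class `precursor_blueprint`.
#' @export
precursor_blueprint <- function(family, peptides, signal_len = 19L,
                                spacer_prob = 0.5, spacer_len = c(4L, 12L),
                                leading_spacer = NA, trailing_spacer = TRUE) {
  stopifnot(signal_len >= 15L)
  structure(list(family = family, peptides = peptides,
                 signal_len = as.integer(signal_len),
                 spacer_prob = spacer_prob,
                 spacer_len = as.integer(spacer_len),
                 leading_spacer = leading_spacer,
                 trailing_spacer = trailing_spacer),
            class = "precursor_blueprint")
}

#' Default blueprint set
#'
#' Emulates the characteristic pentatomid precursor architectures: AKH
#' (single pQLNFSPGW-amide core), myosuppressin (pQ...FLRF-amide), MIP
#' (six W(6x)W-amide plus six W(7x)W-amide paracopies), ETH (three
#' amidated PR[LM] cores), FMRFamide (seven FMRF-amide plus one
#' FIRF-amide), kinin (four FXXWG-amide plus two FSXWA-amide), sulfakinin
#' (GHMRF-amide and GYMRF-amide), FGL-allatostatin (five FGL-amide plus
#' one LGL-amide), RYamide (three conserved cores, one non-amidated), an
#' NPLP1-like precursor (22 segments, three amidated), tachykinin (seven
#' cores) and single-copy CRF-like (44 aa) and calcitonin-like (31 aa)
#' diuretic-hormone cores.
#'
#' @return A named list of [precursor_blueprint()]s.
#' @export
default_blueprints <- function() {
  core <- function(pattern, amidated = TRUE)
    list(pattern = pattern, amidated = amidated)
  rep_core <- function(pattern, k, amidated = TRUE)
    replicate(k, core(pattern, amidated), simplify = FALSE)
  list(
    akh = precursor_blueprint("AKH", list(core("QLNFSPGW")),
                              leading_spacer = FALSE),
    myosuppressin = precursor_blueprint("myosuppressin",
                                        list(core("QDLDHVFLRF"))),
    mip = precursor_blueprint("MIP", c(rep_core("x{2} W x{6} W", 6L),
                                       rep_core("x{2} W x{7} W", 6L))),
    eth = precursor_blueprint("ETH", rep_core("x{7} P R [LM]", 3L)),
    fmrfamide = precursor_blueprint("FMRFamide",
                                    c(rep_core("x{5,7} F M R F", 7L),
                                      rep_core("x{5,7} F I R F", 1L))),
    kinin = precursor_blueprint("kinin",
                                c(rep_core("x{3} F x x W G", 4L),
                                  rep_core("x{3} F S x W A", 2L))),
    sulfakinin = precursor_blueprint("sulfakinin",
                                     list(core("x{2} Y x{2} G H M R F"),
                                          core("x{2} Y x{2} G Y M R F"))),
    fgl_ast = precursor_blueprint("FGL-AST",
                                  c(rep_core("x{4} L G L", 1L),
                                    rep_core("x{4} F G L", 5L))),
    ryamide = precursor_blueprint("RYamide",
                                  list(core("GSDNFFMGSRY"),
                                       core("x{2} F Y x{3} R Y"),
                                       core("SGIFWTGSRYN", FALSE))),
    nplp1_like = precursor_blueprint(
      "NPLP1", lapply(seq_len(22L), function(i)
        core("x{6,12}", amidated = i %in% c(4L, 10L, 16L))),
      spacer_prob = 0, leading_spacer = FALSE, trailing_spacer = FALSE),
    tachykinin = precursor_blueprint("tachykinin",
                                     rep_core("x{4} F x G x R", 7L)),
    crf_dh = precursor_blueprint("CRF-DH", list(core("x{44}")),
                                 leading_spacer = FALSE),
    ct_dh = precursor_blueprint("CT-DH", list(core("x{31}")),
                                leading_spacer = FALSE))
}

# instantiate a motif-language pattern with concrete residues
instantiate_pattern <- function(pattern) {
  src <- gsub("\\s+", "", pattern)
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  out <- character(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      pool <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else if (ch %in% c("X", "x")) {
      pool <- FILL_AA
      i <- i + 1L
    } else {
      pool <- ch
      i <- i + 1L
    }
    reps <- 1L
    if (i <= n && chars[i] == "{") {
      j <- i + 1L
      while (j <= n && chars[j] != "}") j <- j + 1L
      body <- strsplit(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                       ",", fixed = TRUE)[[1]]
      lo <- as.integer(body[1])
      hi <- if (length(body) > 1L) as.integer(body[2]) else lo
      reps <- if (hi > lo) sample(lo:hi, 1L) else lo
      i <- j + 1L
    }
    if (reps > 0L)
      out <- c(out, if (length(pool) > 1L) sample(pool, reps, replace = TRUE)
               else rep(pool, reps))
  }
  paste(out, collapse = "")
}

gen_signal <- function(len) {
  paste0("MK", paste(sample(c("I", "L", "F"), len - 6L, replace = TRUE),
                     collapse = ""), "SAQA")
}

gen_spacer <- function(range) {
  len <- sample(range[1]:range[2], 1L)
  s <- sample(SPACER_AA, len, replace = TRUE)
  if (s[1] == "P") s[1] <- "S" # Pro at +1 would block the upstream site
  paste(s, collapse = "")
}

#' Generate one precursor from a blueprint
#'
#' The instantiated protein is re-annotated with `rules` and only accepted
#' when the annotation reproduces the construction exactly (signal
#' boundary, peptide sequences, amidation); otherwise the draw is repeated
#' (bounded retries).
#'
#' @param blueprint A [precursor_blueprint()].
#' @param id Identifier for the protein record.
#' @param rules The [rule_config()] the precursor must be consistent with.
#' @param seed Optional seed (local RNG).
#' @param max_tries Retry bound.
#' @return A list with `protein` (a [protein_record()]) and `truth` (list:
#'   `id`, `family`, `protein`, `signal_end`, `peptides` - each with
#'   `seq`, `start`, `end`, `amidated`, `pyroglutamate`).
#' @export
generate_precursor <- function(blueprint, id = blueprint$family,
                               rules = rule_config(), seed = NULL,
                               max_tries = 20L) {
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      segs <- list()
      lead <- blueprint$leading_spacer
      if (is.na(lead)) lead <- runif(1) < blueprint$spacer_prob
      if (lead)
        segs[[1L]] <- list(seq = gen_spacer(blueprint$spacer_len),
                           amidated = FALSE)
      for (k in seq_along(blueprint$peptides)) {
        spec <- blueprint$peptides[[k]]
        s <- instantiate_pattern(spec$pattern)
        ch1 <- substr(s, 1L, 1L)
        if (ch1 == "P") # Pro at +1 blocks the upstream cleavage
          s <- paste0(sample(setdiff(FILL_AA, "P"), 1L),
                      substr(s, 2L, nchar(s)))
        segs[[length(segs) + 1L]] <- list(seq = s,
                                          amidated = isTRUE(spec$amidated))
        if (k < length(blueprint$peptides) &&
            runif(1) < blueprint$spacer_prob)
          segs[[length(segs) + 1L]] <- list(
            seq = gen_spacer(blueprint$spacer_len), amidated = FALSE)
      }
      if (blueprint$trailing_spacer)
        segs[[length(segs) + 1L]] <- list(
          seq = gen_spacer(blueprint$spacer_len), amidated = FALSE)
      signal <- gen_signal(blueprint$signal_len)
      parts <- character(0)
      truth_peps <- list()
      cursor <- nchar(signal)
      for (k in seq_along(segs)) {
        seg <- segs[[k]]
        flank <- if (k < length(segs))
          sample(c("KR", "RR"), 1L) else ""
        chunk <- paste0(seg$seq, if (seg$amidated) "G" else "", flank)
        truth_peps[[k]] <- list(
          seq = seg$seq, start = cursor, end = cursor + nchar(seg$seq),
          amidated = seg$amidated,
          pyroglutamate = startsWith(seg$seq, "Q"))
        cursor <- cursor + nchar(chunk)
        parts <- c(parts, chunk)
      }
      prot_seq <- paste0(signal, paste(parts, collapse = ""))
      protein <- protein_record(id, prot_seq, description = blueprint$family)
      model <- annotate_precursor(protein, rules)
      if (annotation_matches_truth(model, blueprint$signal_len, truth_peps))
        return(list(protein = protein,
                    truth = list(id = id, family = blueprint$family,
                                 protein = prot_seq,
                                 signal_end = blueprint$signal_len,
                                 peptides = truth_peps)))
    }
    stop("blueprint '", blueprint$family,
         "' could not be instantiated consistently in ", max_tries,
         " tries (spurious cleavage sites?)")
  })
}

annotation_matches_truth <- function(model, signal_end, truth_peps) {
  if (is.null(model$signal) || model$signal$end != signal_end) return(FALSE)
  if (length(model$peptides) != length(truth_peps)) return(FALSE)
  for (k in seq_along(truth_peps)) {
    p <- model$peptides[[k]]; t <- truth_peps[[k]]
    if (p$seq != t$seq || p$amidated != t$amidated ||
        p$start != t$start || p$end != t$end) return(FALSE)
  }
  TRUE
}

# reverse genetic code: residue -> codons (standard table, no ambiguity)
reverse_code <- function(table = "1") {
  code <- get_codon_table(table)
  split(names(code), unname(code))
}

#' Embed a protein in a synthetic transcript
#'
#' Back-translates with uniform synonymous codon choice, appends a random
#' stop codon, and pads with random UTRs; an in-frame stop is planted
#' immediately 5' of the start codon so the embedded ORF is maximal with
#' exact coordinates. Optionally places the CDS on the reverse strand.
#'
#' @param p A [protein_record()] (no internal stops).
#' @param id Transcript identifier.
#' @param utr5,utr3 UTR lengths; `NULL` draws from `utr_range`.
#' @param strand `"+"` or `"-"`.
#' @param utr_range Range UTR lengths are drawn from.
#' @param seed Optional seed (local RNG).
#' @return A list with `transcript` (a [transcript_record()]), `start`,
#'   `end` (0-based half-open forward-strand CDS coordinates including the
#'   stop codon), `frame`, and `strand`.
#' @export
embed_in_transcript <- function(p, id = p$id, utr5 = NULL, utr3 = NULL,
                                strand = "+", utr_range = c(20L, 80L),
                                seed = NULL) {
  with_seed(seed, {
    rc <- reverse_code()
    aa <- strsplit(sub("\\*$", "", p$seq), "", fixed = TRUE)[[1]]
    codons <- vapply(aa, function(a) {
      pool <- rc[[a]]
      if (is.null(pool)) stop("cannot back-translate residue '", a, "'")
      if (length(pool) > 1L) sample(pool, 1L) else pool
    }, character(1))
    cds <- paste0(paste(codons, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    u5 <- utr5 %||% sample(utr_range[1]:utr_range[2], 1L)
    u3 <- utr3 %||% sample(utr_range[1]:utr_range[2], 1L)
    utr5_seq <- random_nt(u5)
    if (u5 >= 3L) # plant an in-frame stop right before the start codon
      utr5_seq <- paste0(substr(utr5_seq, 1L, u5 - 3L), "TAA")
    full <- paste0(utr5_seq, cds, random_nt(u3))
    start <- u5
    end <- u5 + nchar(cds)
    L <- nchar(full)
    if (strand == "-") {
      # frame -k of the flipped transcript reads the original with offset
      # k-1, so k is set by the CDS offset on the original strand
      frame <- -(start %% 3L + 1L)
      full <- revcomp(full)
      new_start <- L - end
      end <- L - start
      start <- new_start
    } else {
      frame <- start %% 3L + 1L
    }
    list(transcript = transcript_record(id, full), start = start,
         end = end, frame = as.integer(frame), strand = strand)
  })
}

random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Dinucleotide-preserving shuffle of a nucleotide sequence
#'
#' Uniform edge shuffle with an Eulerian walk (retrying when the walk
#' strands early); when no valid walk is found within `max_tries` the
#' sequence is resampled from its first-order Markov (dinucleotide
#' transition) model, which preserves dinucleotide frequencies in
#' expectation.
#'
#' @param seq Nucleotide string.
#' @param seed Optional seed (local RNG).
#' @param max_tries Eulerian-walk retries before the Markov fallback.
#' @return A shuffled string of the same length.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL, max_tries = 50L) {
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 3L) return(seq)
    from <- ch[-n]; to <- ch[-1L]
    for (try in seq_len(max_tries)) {
      adj <- lapply(split(to, from), sample)
      ptr <- lapply(adj, function(x) 1L)
      walk <- character(n); walk[1] <- ch[1]
      v <- ch[1]; ok <- TRUE
      for (i in 2:n) {
        k <- ptr[[v]]
        if (is.null(k) || k > length(adj[[v]])) { ok <- FALSE; break }
        ptr[[v]] <- k + 1L
        v <- adj[[v]][k]
        walk[i] <- v
      }
      if (ok) return(paste(walk, collapse = ""))
    }
    # Markov fallback
    trans <- table(factor(from, c("A", "C", "G", "T", "N")),
                   factor(to, c("A", "C", "G", "T", "N")))
    out <- character(n); out[1] <- ch[1]; v <- ch[1]
    for (i in 2:n) {
      w <- trans[v, ]
      if (sum(w) == 0) w <- rep(1, 5)
      v <- sample(colnames(trans), 1L, prob = w)
      out[i] <- v
    }
    paste(out, collapse = "")
  })
}

#' Mutate a protein toward a given divergence
#'
#' Substitutes each mutable position with probability `divergence`,
#' drawing replacements with BLOSUM62-weighted probabilities
#' (proportional to 2^(score/2)). Positions holding K, R, G or C - the
#' residues that carry cleavage sites, amidation donors and disulfide
#' anchors - are masked and never touched, and are never introduced, so
#' the structural ground truth of the family stays recognizable.
#'
#' @param seq Amino-acid string.
#' @param divergence Substitution fraction in `[0, 0.6]`.
#' @param seed Optional seed (local RNG).
#' @return The mutated string.
#' @export
diverge_protein <- function(seq, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.6)
  if (divergence == 0) return(seq)
  with_seed(seed, {
    B <- blosum62()
    masked <- c("K", "R", "G", "C")
    targets <- setdiff(AA_STANDARD, masked)
    aa <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in seq_along(aa)) {
      a <- aa[i]
      if (a %in% masked || !a %in% AA_STANDARD) next
      if (runif(1) >= divergence) next
      pool <- setdiff(targets, a)
      w <- 2 ^ (B[a, pool] / 2)
      aa[i] <- sample(pool, 1L, prob = w)
    }
    paste(aa, collapse = "")
  })
}

#' Generate a full synthetic dataset with ground truth
#'
#' Builds `n_precursors` precursors by cycling over the blueprints, embeds
#' each in a transcript (random UTRs, random strand), produces a diverged
#' homolog query panel, dinucleotide-shuffled decoy transcripts, and a
#' synthetic MS observation table (theoretical masses of the true mature
#' peptides with seeded ppm jitter and full b/y fragment lists).
#'
#' @param n_precursors Number of embedded precursors.
#' @param n_decoys Number of decoy transcripts.
#' @param divergence Query-panel divergence in `[0, 0.6]`.
#' @param seed Seed pinning the whole dataset.
#' @param blueprints Named list of [precursor_blueprint()]s.
#' @param rules The [rule_config()] precursors are made consistent with.
#' @param utr_range,minus_strand_prob Transcript-embedding options.
#' @param ms_jitter_ppm SD of the precursor-mass jitter (truncated at 3 SD).
#' @param ms_truncation_prob Probability an observation is generated from
#'   the 1-residue C-terminally truncated form.
#' @param ms_min_len Minimum peptide length observed.
#' @return A list: `transcripts`, `decoys`, `panel` (diverged queries with
#'   family descriptions), `truth` (ledger: seed, divergence, precursors,
#'   transcripts incl. decoy flags), `observations` (data frame mz/charge/
#'   fragments), `obs_truth` (the generating peptide and modification
#'   state per observation).
#' @export
generate_dataset <- function(n_precursors = 20L, n_decoys = 200L,
                             divergence = 0.3, seed = 42L,
                             blueprints = default_blueprints(),
                             rules = rule_config(),
                             utr_range = c(20L, 80L),
                             minus_strand_prob = 0.5,
                             ms_jitter_ppm = 10, ms_truncation_prob = 0.1,
                             ms_min_len = 4L) {
  with_seed(seed, {
    n_bp <- length(blueprints)
    transcripts <- vector("list", n_precursors)
    panel <- vector("list", n_precursors)
    truth_prec <- vector("list", n_precursors)
    truth_tx <- list()
    for (i in seq_len(n_precursors)) {
      bp <- blueprints[[(i - 1L) %% n_bp + 1L]]
      pid <- sprintf("prec%02d_%s", i, bp$family)
      gp <- generate_precursor(bp, id = pid, rules = rules)
      strand <- if (runif(1) < minus_strand_prob) "-" else "+"
      tid <- sprintf("tx%03d", i)
      emb <- embed_in_transcript(gp$protein, id = tid, strand = strand,
                                 utr_range = utr_range)
      transcripts[[i]] <- emb$transcript
      truth_prec[[i]] <- gp$truth
      truth_tx[[i]] <- list(id = tid, precursor = pid, frame = emb$frame,
                            start = emb$start, end = emb$end,
                            strand = strand, decoy = FALSE)
      qseq <- diverge_protein(gp$truth$protein, divergence)
      panel[[i]] <- protein_record(sprintf("query%02d_%s", i, bp$family),
                                   qseq, description = bp$family)
    }
    decoys <- vector("list", n_decoys)
    for (j in seq_len(n_decoys)) {
      base <- transcripts[[(j - 1L) %% n_precursors + 1L]]
      did <- sprintf("decoy%03d", j)
      decoys[[j]] <- transcript_record(did,
                                       dinucleotide_shuffle(base$seq))
      truth_tx[[n_precursors + j]] <- list(id = did, precursor = NA,
                                           frame = NA, start = NA,
                                           end = NA, strand = NA,
                                           decoy = TRUE)
    }
    obs <- simulate_observations(truth_prec, ms_jitter_ppm,
                                 ms_truncation_prob, ms_min_len)
    list(transcripts = transcripts, decoys = decoys, panel = panel,
         truth = list(seed = seed, divergence = divergence,
                      precursors = truth_prec, transcripts = truth_tx),
         observations = obs$observations, obs_truth = obs$obs_truth)
  })
}

simulate_observations <- function(truth_prec, jitter_ppm, trunc_prob,
                                  min_len) {
  rows <- list(); truths <- list()
  for (tp in truth_prec) {
    for (k in seq_along(tp$peptides)) {
      pep <- tp$peptides[[k]]
      if (nchar(pep$seq) < min_len) next
      trunc <- if (nchar(pep$seq) > min_len &&
                   runif(1) < trunc_prob) 1L else 0L
      pyro <- pep$pyroglutamate && runif(1) < 0.5
      mods <- modification_state(pep$amidated, pyro,
                                 c_term_truncation = trunc)
      mz <- peptide_mz(pep$seq, mods)
      ppm <- max(-3, min(3, stats::rnorm(1))) * jitter_ppm
      lad <- fragment_ladder(pep$seq, mods)
      frags <- c(lad$b, lad$y) + stats::rnorm(2L * (nchar(pep$seq) -
                                                      trunc - 1L), 0, 0.03)
      rows[[length(rows) + 1L]] <- data.frame(
        mz = mz * (1 + ppm * 1e-6), charge = 1L,
        fragments = paste(sprintf("%.4f", frags), collapse = ";"),
        stringsAsFactors = FALSE)
      truths[[length(truths) + 1L]] <- data.frame(
        precursor = tp$id, copy_index = k, seq = pep$seq,
        amidated = pep$amidated, pyroglutamate = pyro,
        c_term_truncation = trunc, stringsAsFactors = FALSE)
    }
  }
  list(observations = if (length(rows)) do.call(rbind, rows) else
    data.frame(mz = numeric(), charge = integer(), fragments = character()),
    obs_truth = if (length(truths)) do.call(rbind, truths) else NULL)
}

#' Write / read the ground-truth ledger as JSON
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param path JSON file path.
#' @return `path` / the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
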