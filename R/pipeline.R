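# End-to-end orchestration: mine -> annotate -> census -> (ms-match) ->
# (rbh), with per-stage TSV/GFF3/JSON reports.

#' Pipeline run configuration
#'
#' @param transcripts Nucleotide FASTA path or list of
#'   [transcript_record()]s.
#' @param panel Protein FASTA path or list of [protein_record()]s (query
#'   panel; families taken from descriptions).
#' @param out_dir Output directory (created if missing).
#' @param observations Optional observation TSV path or data frame.
#' @param proteome_b Optional second proteome (path or records) for RBH
#'   orthology against the mined precursor proteins.
#' @param seed Seed for any stochastic step.
#' @param scheme A [scoring_scheme()].
#' @param min_score,min_identity,min_orf_aa,max_rounds Mining thresholds,
#'   see [mine_sequences()].
#' @param rules A [rule_config()].
#' @param motif_library List of `motif_spec`s.
#' @param tol_ppm,frag_tol_da MS matching tolerances.
#' @return An object of class `run_config`.
#' @export
run_config <- function(transcripts, panel, out_dir,
                       observations = NULL, proteome_b = NULL, seed = 1L,
                       scheme = scoring_scheme(), min_score = 50L,
                       min_identity = 0.3, min_orf_aa = 30L,
                       max_rounds = 1L, rules = rule_config(),
                       motif_library = default_motif_library(),
                       tol_ppm = 50, frag_tol_da = 0.3) {
  for (x in list(transcripts, panel, observations, proteome_b))
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop("config error: no such file: ", x)
  structure(list(transcripts = transcripts, panel = panel,
                 out_dir = out_dir, observations = observations,
                 proteome_b = proteome_b, seed = as.integer(seed),
                 scheme = scheme, min_score = min_score,
                 min_identity = min_identity, min_orf_aa = min_orf_aa,
                 max_rounds = max_rounds, rules = rules,
                 motif_library = motif_library, tol_ppm = tol_ppm,
                 frag_tol_da = frag_tol_da),
            class = "run_config")
}

load_stage <- function(x, loader) if (is.character(x)) loader(x) else x

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: translated mining, precursor annotation of every accepted ORF,
#' motif census and family classification, optional MS matching, optional
#' RBH orthology. Reports (TSV/GFF3) and a machine-readable `summary.json`
#' are written under `cfg$out_dir`. Re-running with the same configuration
#' and inputs reproduces the outputs byte-identically.
#'
#' @param cfg A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  transcripts <- stage("load", load_stage(cfg$transcripts,
                                          function(p) read_fasta(p, "nt")))
  panel <- stage("load", load_stage(cfg$panel,
                                    function(p) read_fasta(p, "aa")))
  results <- stage("mine", mine_sequences(
    transcripts, panel, scheme = cfg$scheme, min_score = cfg$min_score,
    min_identity = cfg$min_identity, min_orf_aa = cfg$min_orf_aa,
    max_rounds = cfg$max_rounds))
  write_tsv(hits_table(results), file.path(cfg$out_dir, "hits.tsv"))
  write_hits_gff3(results, file.path(cfg$out_dir, "hits.gff3"))

  models <- stage("annotate", {
    got <- Filter(function(r) !is.null(r$orf), results)
    lapply(got, function(r)
      annotate_precursor(r$orf$protein, rules = cfg$rules,
                         complete_c_terminus = r$orf$has_stop,
                         family = r$family))
  })
  write_tsv(peptide_table(models), file.path(cfg$out_dir, "peptides.tsv"))
  write_precursor_gff3(models, file.path(cfg$out_dir, "precursors.gff3"))

  census <- stage("census", motif_census(models, cfg$motif_library))
  write_tsv(census, file.path(cfg$out_dir, "census.tsv"))

  matches <- NULL
  if (!is.null(cfg$observations)) {
    obs <- stage("ms-match", load_stage(cfg$observations, read_observations))
    peps <- unlist(lapply(models, `[[`, "peptides"), recursive = FALSE)
    matches <- stage("ms-match", match_observations(
      obs, peps, tol_ppm = cfg$tol_ppm, frag_tol_da = cfg$frag_tol_da))
    write_tsv(matches, file.path(cfg$out_dir, "ms_matches.tsv"))
  }

  orthologs <- NULL
  if (!is.null(cfg$proteome_b)) {
    pb <- stage("rbh", load_stage(cfg$proteome_b,
                                  function(p) read_fasta(p, "aa")))
    pa <- lapply(models, `[[`, "protein")
    orthologs <- stage("rbh", rbh_orthologs(pa, pb, scheme = cfg$scheme))
    write_tsv(orthologs, file.path(cfg$out_dir, "orthologs.tsv"))
  }

  fam <- vapply(models, function(m) m$family %||% "unassigned", character(1))
  pep_counts <- vapply(models, function(m) length(m$peptides), integer(1))
  ami_counts <- vapply(models, function(m)
    sum(vapply(m$peptides, `[[`, logical(1), "amidated")), integer(1))
  fam_tab <- if (length(fam)) {
    agg <- stats::aggregate(
      cbind(precursors = rep(1L, length(fam)), peptides = pep_counts,
            amidated = ami_counts) ~ family, data = data.frame(
              family = fam, stringsAsFactors = FALSE), FUN = sum)
    agg[order(agg$family), , drop = FALSE]
  } else data.frame(family = character(), precursors = integer(),
                    peptides = integer(), amidated = integer())
  write_tsv(fam_tab, file.path(cfg$out_dir, "summary.tsv"))
  summary <- list(
    n_transcripts = length(transcripts), n_hits = length(results),
    n_precursors = length(models),
    families = stats::setNames(as.list(fam_tab$precursors), fam_tab$family),
    n_peptides = sum(pep_counts), n_amidated = sum(ami_counts),
    n_ms_matches = if (is.null(matches)) NA else
      length(unique(matches$obs_index)),
    n_reciprocal_orthologs = if (is.null(orthologs)) NA else
      sum(orthologs$reciprocal))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(summary)
}
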