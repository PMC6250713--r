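test_that("annotation recovers the construction for every shipped blueprint", {
  bps <- default_blueprints()
  for (nm in names(bps)) {
    gp <- generate_precursor(bps[[nm]], seed = 901L)
    m <- annotate_precursor(gp$protein)
    expect_equal(m$signal$end, gp$truth$signal_end, info = nm)
    expect_length(m$peptides, length(gp$truth$peptides))
    for (k in seq_along(gp$truth$peptides)) {
      tp <- gp$truth$peptides[[k]]
      expect_equal(m$peptides[[k]]$seq, tp$seq, info = nm)
      expect_equal(m$peptides[[k]]$amidated, tp$amidated, info = nm)
      expect_equal(m$peptides[[k]]$pyroglutamate, tp$pyroglutamate,
                   info = nm)
      expect_equal(c(m$peptides[[k]]$start, m$peptides[[k]]$end),
                   c(tp$start, tp$end), info = nm)
    }
  }
})

test_that("a zero-peptide blueprint degenerates to a single propeptide", {
  bp <- precursor_blueprint("empty", peptides = list(),
                            leading_spacer = FALSE)
  gp <- generate_precursor(bp, seed = 902L)
  m <- annotate_precursor(gp$protein)
  expect_length(m$peptides, 1L)
  expect_false(m$peptides[[1]]$amidated)
})

test_that("datasets are byte-identical under a fixed seed", {
  d1 <- generate_dataset(n_precursors = 4L, n_decoys = 6L,
                         divergence = 0.25, seed = 99L)
  d2 <- generate_dataset(n_precursors = 4L, n_decoys = 6L,
                         divergence = 0.25, seed = 99L)
  expect_identical(lapply(d1$transcripts, `[[`, "seq"),
                   lapply(d2$transcripts, `[[`, "seq"))
  expect_identical(lapply(d1$decoys, `[[`, "seq"),
                   lapply(d2$decoys, `[[`, "seq"))
  expect_identical(lapply(d1$panel, `[[`, "seq"),
                   lapply(d2$panel, `[[`, "seq"))
  expect_identical(d1$observations, d2$observations)
  d3 <- generate_dataset(n_precursors = 4L, n_decoys = 6L,
                         divergence = 0.25, seed = 100L)
  expect_false(identical(lapply(d1$transcripts, `[[`, "seq"),
                         lapply(d3$transcripts, `[[`, "seq")))
})

test_that("embedding with zero UTRs is the bare back-translation", {
  gp <- generate_precursor(default_blueprints()$akh, seed = 903L)
  emb <- embed_in_transcript(gp$protein, utr5 = 0L, utr3 = 0L,
                             strand = "+", seed = 904L)
  expect_equal(emb$start, 0L)
  expect_equal(emb$end, nchar(emb$transcript$seq))
  aa <- six_frame_translate(emb$transcript)[["+1"]]$seq
  expect_equal(aa, paste0(gp$protein$seq, "*"))
})

test_that("reverse-strand embeddings are recovered through frame -k", {
  gp <- generate_precursor(default_blueprints()$sulfakinin, seed = 905L)
  emb <- embed_in_transcript(gp$protein, strand = "-", seed = 906L)
  expect_lt(emb$frame, 0L)
  fr <- six_frame_translate(emb$transcript)[[sprintf("%+d", emb$frame)]]
  expect_true(grepl(gp$protein$seq, fr$seq, fixed = TRUE))
  # stored coordinates satisfy the ORF-call consistency invariant
  slice <- revcomp(substr(emb$transcript$seq, emb$start + 1L, emb$end))
  aa <- six_frame_translate(transcript_record("s", slice))[["+1"]]$seq
  expect_equal(aa, paste0(gp$protein$seq, "*"))
})

test_that("dinucleotide shuffles preserve length, composition and doublets", {
  set.seed(907)
  for (i in 1:10) {
    s <- random_transcript(sample(60:300, 1))
    sh <- dinucleotide_shuffle(s, seed = 908L + i)
    expect_equal(nchar(sh), nchar(s))
    count_dinuc <- function(x) {
      ch <- strsplit(x, "")[[1]]
      table(factor(paste0(ch[-length(ch)], ch[-1]),
                   levels = as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"),
                                            paste0))))
    }
    expect_equal(count_dinuc(sh), count_dinuc(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("divergence masks K/R/G/C and hits the requested rate", {
  set.seed(909)
  s <- random_protein(4000)
  out <- diverge_protein(s, 0.3, seed = 910L)
  a <- strsplit(s, "")[[1]]; b <- strsplit(out, "")[[1]]
  masked <- a %in% c("K", "R", "G", "C")
  expect_true(all(a[masked] == b[masked]))
  expect_false(any(b[!masked] %in% c("K", "R", "G", "C") &
                     b[!masked] != a[!masked]))
  rate <- mean(a[!masked] != b[!masked])
  expect_gt(rate, 0.25); expect_lt(rate, 0.35)
  expect_equal(diverge_protein(s, 0), s)
  expect_error(diverge_protein(s, 0.7), "divergence")
})

test_that("at divergence zero mining recovers every embedded locus", {
  d <- generate_dataset(n_precursors = 5L, n_decoys = 0L, divergence = 0,
                        seed = 911L)
  res <- mine_sequences(d$transcripts, d$panel, min_score = 76L)
  ev <- evaluate_mining(res, d$truth)
  expect_equal(ev$recall, 1)
})

test_that("the truth ledger round-trips losslessly through JSON", {
  d <- generate_dataset(n_precursors = 3L, n_decoys = 2L,
                        divergence = 0.2, seed = 912L)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(d$truth, f)
  back <- read_truth(f)
  reser <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                        null = "null", na = "null")
  expect_equal(reser(back), reser(d$truth))
})
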