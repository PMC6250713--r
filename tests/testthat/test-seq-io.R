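test_that("FASTA reading handles minimal, empty and lowercase input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), f)
  recs <- read_fasta(f, "nt")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$seq, "ACGT")

  writeLines(character(0), f)
  expect_length(read_fasta(f, "nt"), 0L)

  writeLines(c(">lc", "acgt"), f)
  expect_equal(read_fasta(f, "nt")[[1]]$seq, "ACGT")
})

test_that("FASTA errors name the offending record", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f, "nt"), "duplicate record id 'a'")
  writeLines(c(">b", "ACQT"), f)
  expect_error(read_fasta(f, "nt"), "record 'b' at position 3")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa"), "nt"),
               "no such file")
})

test_that("FASTA round-trips generated datasets identically", {
  set.seed(301)
  recs <- lapply(1:8, function(i)
    transcript_record(sprintf("t%02d", i), random_transcript(50 + 7 * i),
                      description = if (i %% 2) "some description" else ""))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f, width = 60L)
  back <- read_fasta(f, "nt")
  expect_equal(back, recs)
  # wrap-width must not matter
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(back, f2, width = 11L)
  expect_equal(read_fasta(f2, "nt"), recs)
})

test_that("reverse complement is an involution and matches frame -k", {
  set.seed(302)
  for (i in 1:20) {
    s <- random_transcript(sample(3:120, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
  t <- transcript_record("t", random_transcript(100))
  trc <- transcript_record("t_rc", revcomp(t$seq))
  fr <- six_frame_translate(t)
  fr_rc <- six_frame_translate(trc)
  for (k in 1:3)
    expect_equal(fr[[sprintf("%+d", -k)]]$seq,
                 fr_rc[[sprintf("%+d", k)]]$seq)
})

test_that("six-frame translation follows the standard code and maps Ns to X", {
  t <- transcript_record("x", "ATGGGA")
  fr <- six_frame_translate(t)
  expect_equal(fr[["+1"]]$seq, "MG")
  expect_equal(fr[["+2"]]$seq, "W")
  tn <- transcript_record("n", "ATGNNATAA")
  expect_equal(six_frame_translate(tn)[["+1"]]$seq, "MX*")
  expect_error(six_frame_translate(transcript_record("s", "AT")),
               "shorter than one codon")
})

test_that("find_orfs reports the complete Met ORF with exact bounds", {
  o <- find_orfs(transcript_record("y", "ATGAAATAG"), min_aa = 2L)
  complete <- Filter(function(x) x$has_start && x$has_stop, o)
  expect_length(complete, 1L)
  expect_equal(complete[[1]]$protein$seq, "MK")
  expect_equal(c(complete[[1]]$start, complete[[1]]$end), c(0L, 9L))
  expect_equal(complete[[1]]$frame, 1L)
})

test_that("a stopless, Met-less transcript yields one partial ORF per frame", {
  o <- find_orfs(transcript_record("a", strrep("A", 33)), min_aa = 2L)
  expect_length(o, 6L)
  expect_true(all(!vapply(o, `[[`, logical(1), "has_start")))
  expect_true(all(!vapply(o, `[[`, logical(1), "has_stop")))
})

test_that("ORF calls satisfy the retranslation invariant", {
  set.seed(303)
  for (i in 1:10) {
    t <- transcript_record(paste0("t", i), random_transcript(200))
    for (o in find_orfs(t, min_aa = 5L)) {
      expect_equal((o$end - o$start) %% 3L, 0L)
      slice <- substr(t$seq, o$start + 1L, o$end)
      if (o$frame < 0) slice <- revcomp(slice)
      aa <- six_frame_translate(
        transcript_record("s", slice))[["+1"]]$seq
      expect_equal(sub("\\*$", "", aa), o$protein$seq)
      expect_equal(o$has_stop, endsWith(aa, "*"))
    }
  }
})

test_that("embedded synthetic ORFs are recovered with exact coordinates", {
  bp <- default_blueprints()
  for (s in c(5, 17)) {
    gp <- generate_precursor(bp$eth, seed = s)
    for (strand in c("+", "-")) {
      emb <- embed_in_transcript(gp$protein, strand = strand, seed = s)
      orfs <- find_orfs(emb$transcript, min_aa = 30L)
      hit <- Filter(function(o)
        o$start == emb$start && o$end == emb$end && o$frame == emb$frame,
        orfs)
      expect_length(hit, 1L)
      expect_equal(hit[[1]]$protein$seq, gp$protein$seq)
      expect_true(hit[[1]]$has_start && hit[[1]]$has_stop)
    }
  }
})

test_that("GFF3 export converts to 1-based inclusive coordinates", {
  o <- find_orfs(transcript_record("y", "ATGAAATAG"), min_aa = 2L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_orf_gff3(o, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  complete <- grep("has_start=true;has_stop=true", lines, value = TRUE)
  fields <- strsplit(complete, "\t")[[1]]
  expect_equal(as.integer(fields[4:5]), c(1L, 9L))
})
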