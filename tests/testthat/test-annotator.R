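test_that("signal peptides are detected at the generated boundary", {
  # canonical architecture: M + charged n-region, hydrophobic core,
  # small residues at -3 and -1
  p <- paste0(demo_signal, "QLNFSPGWGKRSDNAEQTD")
  sp <- predict_signal_peptide(p)
  expect_equal(sp$end, 15L)
  # generator-built signals across blueprints
  bp <- default_blueprints()
  for (nm in c("akh", "mip", "tachykinin")) {
    gp <- generate_precursor(bp[[nm]], seed = 61L)
    sp <- predict_signal_peptide(gp$protein$seq)
    expect_equal(sp$end, bp[[nm]]$signal_len)
  }
})

test_that("signal prediction refuses sequences without a hydrophobic core", {
  expect_null(predict_signal_peptide(strrep("S", 40)))
  # N-terminally truncated precursor: no Met, no hydrophobic stretch
  trunc <- paste0(strrep("DNSEQ", 8), "GKR", strrep("ASTE", 4))
  expect_null(predict_signal_peptide(trunc))
  m <- annotate_precursor(trunc)
  expect_false(m$flags$complete_n_terminus)
})

test_that("dibasic KR sites enable amidated FMRF-type peptides", {
  p <- paste0(demo_signal, "SDNFMRFG", "KR", "ASTEQDNSA")
  m <- annotate_precursor(p)
  site <- m$sites[[1]]
  expect_equal(site$kind, "dibasic")
  expect_equal(site$motif, "KR")
  expect_equal(site$basic_run, 2L)
  pep <- m$peptides[[1]]
  expect_equal(pep$seq, "SDNFMRF")
  expect_true(pep$amidated)
})

test_that("a sequence without basics has only the terminus site", {
  sites <- predict_cleavage_sites("AAAPAAA")
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$kind, "terminus")
  expect_equal(sites[[1]]$position, 7L)
})

test_that("proline at +1 blocks cleavage", {
  sites <- predict_cleavage_sites("AAAGKRPAAA")
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$kind, "terminus")
})

test_that("monobasic R needs basic support at -4, -6 or -8; K never cleaves", {
  # K at 0-based 3 supports R at 6 (offset -4 from the bond after R)
  s1 <- predict_cleavage_sites("AAAKAARAAAA")
  expect_equal(vapply(s1, `[[`, character(1), "kind"),
               c("monobasic", "terminus"))
  expect_equal(s1[[1]]$position, 7L)
  # no upstream basic: nothing but the terminus
  s2 <- predict_cleavage_sites("AAAAAARAAAA")
  expect_length(s2, 1L)
  # lone K with support is never cleaved
  s3 <- predict_cleavage_sites("AAAKAAKAAAA")
  expect_length(s3, 1L)
})

test_that("KK obeys its switch and basic runs collapse to one site", {
  expect_length(predict_cleavage_sites("AAAAKKAAAA"), 1L) # terminus only
  s <- predict_cleavage_sites("AAAAKKAAAA",
                              rules = rule_config(cleave_kk = TRUE))
  expect_equal(s[[1]]$kind, "dibasic")
  expect_equal(s[[1]]$motif, "KK")
  t <- predict_cleavage_sites("AAAARKRRAAAA")
  expect_equal(t[[1]]$kind, "tetrabasic")
  expect_equal(t[[1]]$basic_run, 4L)
  expect_equal(t[[1]]$position, 8L)
})

test_that("no cleavage site falls inside or just after the signal peptide", {
  # the R at position 14 of the signal must not seed a site
  p <- paste0(demo_signal, "AAAADNSEQAAAKRAASTEQ")
  m <- annotate_precursor(p)
  pos <- vapply(m$sites, `[[`, integer(1), "position")
  expect_true(all(pos > 15L + 3L | pos == nchar(p)))
})

test_that("an AKH-like precursor derives pQLNFSPGW-amide", {
  p <- paste0(demo_signal, "QLNFSPGW", "G", "KR", "SDNAEQTDASNE")
  m <- annotate_precursor(p)
  pep <- m$peptides[[1]]
  expect_equal(pep$seq, "QLNFSPGW")
  expect_true(pep$amidated)
  expect_true(pep$pyroglutamate)
  expect_equal(pep$copy_index, 1L)
})

test_that("a precursor without internal sites is one whole propeptide", {
  p <- paste0(demo_signal, "ASTEQDNSAHTESDNA")
  m <- annotate_precursor(p)
  expect_length(m$peptides, 1L)
  expect_equal(m$peptides[[1]]$seq, "ASTEQDNSAHTESDNA")
  expect_false(m$peptides[[1]]$amidated)
})

test_that("degenerate short input yields a signal-less single-peptide model", {
  m <- annotate_precursor("AQTDSPAW")
  expect_null(m$signal)
  expect_false(m$flags$complete_n_terminus)
  expect_length(m$peptides, 1L)
  expect_equal(m$peptides[[1]]$seq, "AQTDSPAW")
})

test_that("site positions match the predicate-enumeration oracle on random sequences", {
  set.seed(601)
  for (i in 1:150) {
    s <- random_protein(sample(20:60, 1))
    got <- vapply(predict_cleavage_sites(s), `[[`, integer(1), "position")
    expect_equal(got, oracle_cleavage_positions(s), info = s)
  }
  # and under a signal guard
  for (i in 1:50) {
    s <- paste0(demo_signal, random_protein(sample(10:45, 1)))
    sp <- list(start = 0L, end = 15L)
    got <- vapply(predict_cleavage_sites(s, signal = sp), `[[`,
                  integer(1), "position")
    expect_equal(got, oracle_cleavage_positions(s, signal_end = 15L),
                 info = s)
  }
})

test_that("sequence conservation holds under fuzzing", {
  set.seed(602)
  for (i in 1:200) {
    s <- random_protein(sample(5:60, 1))
    m <- annotate_precursor(s)
    expect_equal(reconstruct_precursor(m), s, info = s)
  }
  # and for every shipped blueprint
  for (bp in default_blueprints()) {
    gp <- generate_precursor(bp, seed = 603L)
    m <- annotate_precursor(gp$protein)
    expect_equal(reconstruct_precursor(m), gp$protein$seq)
  }
})

test_that("amidation consumes exactly one glycine and never leaves one", {
  set.seed(604)
  for (i in 1:100) {
    s <- random_protein(sample(10:60, 1))
    m <- annotate_precursor(s)
    for (pep in m$peptides) {
      if (pep$amidated) {
        expect_equal(substr(s, pep$end + 1L, pep$end + 1L), "G")
        expect_false(endsWith(pep$seq, "G") &&
                       substr(s, pep$end + 1L, pep$end + 1L) != "G")
      }
    }
  }
})

test_that("appending C-terminal residues never changes upstream peptides", {
  set.seed(605)
  for (i in 1:60) {
    s <- random_protein(sample(20:50, 1))
    m1 <- annotate_precursor(s)
    m2 <- annotate_precursor(paste0(s, "QANA"))
    k <- length(m1$peptides) - 1L
    if (k >= 1) for (j in seq_len(k)) {
      expect_equal(m2$peptides[[j]]$seq, m1$peptides[[j]]$seq)
      expect_equal(m2$peptides[[j]]$amidated, m1$peptides[[j]]$amidated)
    }
  }
})

test_that("an external signal span overrides the heuristic", {
  p <- paste0(demo_signal, "QLNFSPGWGKRSDNAEQTD")
  m <- annotate_precursor(p, signal = list(start = 0L, end = 18L))
  expect_equal(m$signal$end, 18L)
  expect_equal(m$peptides[[1]]$start, 18L)
})
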