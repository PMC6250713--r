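test_that("monoisotopic masses and modification deltas are exact", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  set.seed(801)
  for (i in 1:20) {
    s <- random_protein(sample(2:25, 1))
    free <- peptide_mass(s)
    expect_equal(peptide_mass(s, modification_state(amidated = TRUE)) -
                   free, -0.984016, tolerance = 1e-9)
    q <- paste0("Q", s)
    expect_equal(peptide_mass(q, modification_state(pyroglutamate = TRUE)) -
                   peptide_mass(q), -17.026549, tolerance = 1e-9)
    y <- paste0(s, "Y")
    expect_equal(peptide_mass(y, modification_state(sulfation_count = 1L)) -
                   peptide_mass(y), 79.956815, tolerance = 1e-9)
    expect_equal(peptide_mass(paste0(s, "W"),
                              modification_state(c_term_truncation = 1L)),
                 peptide_mass(s), tolerance = 1e-9)
  }
  expect_error(peptide_mass("AZA"), "nonstandard residue 'Z' at position 2")
  expect_error(peptide_mass("AAA", modification_state(pyroglutamate = TRUE)),
               "pyroglutamate")
  expect_error(peptide_mass("AAA", modification_state(sulfation_count = 1L)),
               "sulfation")
})

test_that("mass is additive over concatenation", {
  set.seed(802)
  for (i in 1:25) {
    a <- random_protein(sample(1:15, 1))
    b <- random_protein(sample(1:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("b/y ladders satisfy the complementarity identity", {
  lad <- fragment_ladder("GG")
  expect_equal(lad$b[1], 58.02874, tolerance = 1e-5)
  set.seed(803)
  for (i in 1:40) {
    s <- random_protein(sample(2:20, 1))
    mods <- modification_state(
      amidated = runif(1) < 0.5,
      pyroglutamate = FALSE,
      sulfation_count = 0L, c_term_truncation = 0L)
    if (runif(1) < 0.3) {
      s <- paste0("Q", s)
      mods$pyroglutamate <- TRUE
    }
    lad <- fragment_ladder(s, mods)
    n <- nchar(s)
    precursor <- peptide_mass(s, mods)
    for (j in seq_len(n - 1L))
      expect_equal(lad$b[j] + lad$y[n - j] - 2 * 1.007276, precursor,
                   tolerance = 1e-4)
  }
  expect_error(fragment_ladder("A"), "at least 2")
})

test_that("amidation shifts every y ion and no b ion", {
  set.seed(804)
  for (i in 1:10) {
    s <- random_protein(sample(3:15, 1))
    free <- fragment_ladder(s)
    amide <- fragment_ladder(s, modification_state(amidated = TRUE))
    expect_equal(amide$b, free$b)
    expect_equal(amide$y, free$y - 0.984016)
  }
})

ms_core <- make_pep("QDLDHVFLRF", amidated = TRUE)

test_that("a pQ-amidated myosuppressin-type core is matched with its mods", {
  mz <- peptide_mz("QDLDHVFLRF",
                   modification_state(amidated = TRUE,
                                      pyroglutamate = TRUE))
  obs <- data.frame(mz = mz, charge = 1L)
  mt <- match_observations(obs, list(ms_core))
  expect_gte(nrow(mt), 1L)
  top <- mt[mt$rank == 1L, ]
  expect_equal(top$seq, "QDLDHVFLRF")
  expect_true(top$amidated)
  expect_true(top$pyroglutamate)
  expect_lt(abs(top$ppm), 1e-6)
})

test_that("C-terminally truncated forms are recognized", {
  nvp <- make_pep("NVPIYQEPSA", amidated = FALSE)
  mz <- peptide_mz("NVPIYQEPSA",
                   modification_state(c_term_truncation = 1L))
  mt <- match_observations(data.frame(mz = mz, charge = 1L), list(nvp),
                           mod_space = list(sulfation = FALSE))
  top <- mt[mt$rank == 1L, ]
  expect_equal(top$c_term_truncation, 1L)
})

test_that("empty observation lists give empty results", {
  mt <- match_observations(data.frame(mz = numeric(0)), list(ms_core))
  expect_equal(nrow(mt), 0L)
})

test_that("observations within tolerance are always recovered", {
  set.seed(805)
  for (i in 1:20) {
    s <- random_protein(sample(5:18, 1))
    pep <- make_pep(s, amidated = runif(1) < 0.5)
    x <- runif(1, -45, 45) # ppm, inside the 50 ppm window
    mz <- peptide_mz(s, modification_state(amidated = pep$amidated)) *
      (1 + x * 1e-6)
    mt <- match_observations(data.frame(mz = mz, charge = 1L), list(pep),
                             tol_ppm = 50)
    expect_true(any(mt$seq == s & mt$amidated == pep$amidated))
  }
})

test_that("fragment evidence promotes the generating modification state", {
  s <- "QASNFTDWLER"
  mods <- modification_state(pyroglutamate = TRUE)
  lad <- fragment_ladder(s, mods)
  obs <- data.frame(mz = peptide_mz(s, mods), charge = 1L,
                    fragments = paste(sprintf("%.4f", c(lad$b, lad$y)),
                                      collapse = ";"))
  mt <- match_observations(obs, list(make_pep(s)),
                           mod_space = list(sulfation = FALSE))
  top <- mt[mt$rank == 1L, ]
  expect_true(top$pyroglutamate)
  expect_equal(top$frag_matched, top$frag_total)
})

test_that("observation readers parse TSV and MGF", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tcharge\tfragments",
               "930.4468\t1\t58.0287;115.0502"), f)
  obs <- read_observations(f)
  expect_equal(obs$mz, 930.4468)
  g <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=spec1", "PEPMASS=930.4468", "CHARGE=1+",
               "58.0287 100", "115.0502 40", "END IONS"), g)
  mgf <- read_mgf(g)
  expect_equal(mgf$mz, 930.4468)
  expect_equal(mgf$fragments, "58.0287;115.0502")
  writeLines("mz_missing\t1", f)
  expect_error(read_observations(f), "mz")
})
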