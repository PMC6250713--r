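# Independent oracles used to validate the implementation, written as
# different algorithms on purpose: they share no code with the package
# internals they check.

# ---- local alignment oracle -------------------------------------------
# Best local score = max over all substring pairs of a GLOBAL affine-gap
# alignment score, computed by memoized recursion over three end states.
# Gap of length L costs open + L * extend (positive costs).
oracle_global_affine <- function(a, b, mat, open, extend) {
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    # best score of aligning a[1..i] vs b[1..j], last column type `state`
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      if (state == "M") 0 else -Inf
    } else if (state == "M") {
      if (i == 0 || j == 0) -Inf
      else max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "U"),
               rec(i - 1, j - 1, "L")) + mat[ca[i], cb[j]]
    } else if (state == "U") { # gap in b, consumes a[i]
      if (i == 0) -Inf
      else max(rec(i - 1, j, "M") - open - extend,
               rec(i - 1, j, "L") - open - extend,
               rec(i - 1, j, "U") - extend)
    } else { # "L": gap in a, consumes b[j]
      if (j == 0) -Inf
      else max(rec(i, j - 1, "M") - open - extend,
               rec(i, j - 1, "U") - open - extend,
               rec(i, j - 1, "L") - extend)
    }
    memo[[key]] <- val
    val
  }
  max(rec(na, nb, "M"), rec(na, nb, "U"), rec(na, nb, "L"))
}

oracle_local_score <- function(a, b, mat, open = 11, extend = 1) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- oracle_global_affine(substr(a, i1, i2), substr(b, j1, j2),
                                mat, open, extend)
      if (s > best) best <- s
    }
  best
}

# ---- cleavage-site oracle ---------------------------------------------
# Enumerates every K/R position and applies each rule predicate
# independently; returns sorted 0-based cleavage positions (terminus
# included unless a basic site already falls there).
oracle_cleavage_positions <- function(seq, signal_end = 0L,
                                      dibasic = c("KR", "RR", "RK"),
                                      offsets = c(4L, 6L, 8L)) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  guard <- if (signal_end > 0L) signal_end + 3L else 0L
  out <- integer(0)
  for (i in seq_len(n)) { # 1-based index of a candidate run-terminal K/R
    if (!aa[i] %in% c("K", "R")) next
    if (i < n && aa[i + 1] %in% c("K", "R")) next # not the run end
    j <- i
    while (j > 1 && aa[j - 1] %in% c("K", "R")) j <- j - 1
    if (j <= guard) next
    pos <- i # 0-based cleavage position equals the 1-based run-end index
    if (pos < n && aa[pos + 1] == "P") next
    run <- i - j + 1L
    ok <- if (run == 1L) {
      aa[i] == "R" && any(vapply(offsets, function(o)
        pos - o >= 0L && aa[pos - o + 1L] %in% c("K", "R"), logical(1)))
    } else if (run == 2L) {
      paste0(aa[j], aa[i]) %in% dibasic
    } else TRUE
    if (ok) out <- c(out, pos)
  }
  sort(unique(c(out, n)))
}

# ---- naive motif matcher ----------------------------------------------
# Tokens: list of list(pool = character vector or "ANY", lo, hi).
# Tries every start position and every repeat-count combination.
naive_motif_match <- function(tokens, seq, anchor = "c_terminal") {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  if (n == 0L) return(FALSE)
  # can tokens ti.. match at position pos, subject to the end condition?
  rec <- function(pos, ti, must_end) {
    if (ti > length(tokens))
      return(if (must_end) pos == n + 1L else TRUE)
    tk <- tokens[[ti]]
    for (reps in tk$lo:tk$hi) {
      if (pos + reps - 1L > n) next
      ok <- TRUE
      if (reps > 0) for (k in 0:(reps - 1L)) {
        ch <- aa[pos + k]
        if (!(identical(tk$pool, "ANY") || ch %in% tk$pool)) {
          ok <- FALSE; break
        }
      }
      if (ok && rec(pos + reps, ti + 1L, must_end)) return(TRUE)
    }
    FALSE
  }
  # n+1 admits empty matches at the C-terminal boundary, as regexes do
  starts <- if (anchor %in% c("n_terminal", "both")) 1L
            else seq_len(n + 1L)
  must_end <- anchor %in% c("c_terminal", "both")
  any(vapply(starts, function(s) rec(s, 1L, must_end), logical(1)))
}

# render a token list in the package's pattern language
tokens_to_pattern <- function(tokens) {
  paste(vapply(tokens, function(tk) {
    base <- if (identical(tk$pool, "ANY")) "x"
            else if (length(tk$pool) == 1L) tk$pool
            else paste0("[", paste(tk$pool, collapse = ""), "]")
    if (tk$lo == 1L && tk$hi == 1L) base
    else if (tk$lo == tk$hi) paste0(base, "{", tk$lo, "}")
    else paste0(base, "{", tk$lo, ",", tk$hi, "}")
  }, character(1)), collapse = " ")
}

random_tokens <- function(n_tokens) {
  lapply(seq_len(n_tokens), function(i) {
    kind <- sample(3, 1)
    pool <- switch(kind,
                   "ANY",
                   sample(c("A", "S", "W", "F", "G", "L", "R"), 1),
                   sample(c("A", "S", "W", "F", "G", "L"),
                          sample(2:3, 1)))
    lo <- sample(0:2, 1)
    hi <- lo + sample(0:2, 1)
    if (lo == 0 && hi == 0) hi <- 1
    list(pool = pool, lo = lo, hi = hi)
  })
}

# ---- misc helpers ------------------------------------------------------
random_protein <- function(n, alphabet = names(npmine:::AA_MONO)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_transcript <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a canonical signal peptide for fixtures: hydrophobic core, small
# residues at -3/-1, and no basic residue that could license a monobasic
# site just downstream
demo_signal <- "MKTLVLLAVLACASA"
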