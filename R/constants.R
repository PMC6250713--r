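# Physical constants and residue tables.
#
# Monoisotopic residue masses (Da) for the 20 standard amino acids; the
# peptide neutral mass is the residue sum plus one water. Values agree with
# the standard elemental composition to 1e-6 Da.

AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MONO  <- 18.010565
PROTON_MASS <- 1.007276
# post-translational mass deltas
AMIDE_DELTA   <- -0.984016   # C-terminal amide vs free acid (O+H -> N+H2)
PYROGLU_DELTA <- -17.026549  # N-terminal Gln cyclization (NH3 loss)
SULFO_DELTA   <- +79.956815  # tyrosine O-sulfation (SO3)

# Kyte-Doolittle hydropathy index, used by the signal-peptide heuristic.
KD_HYDROPATHY <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# residues counted as "small/neutral" at the signal-peptidase (-3,-1) positions
SIGNAL_SMALL <- c("A", "G", "S", "C", "T", "V")

AA_STANDARD <- names(AA_MONO)

blosum62_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 scoring matrix (24 x 24, including B, Z, X and `*`)
#' as shipped with Biostrings, cached after first use.
#'
#' @return An integer matrix with residue row/column names.
#' @export
blosum62 <- function() {
  if (is.null(blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$mat <- e$BLOSUM62
  }
  blosum62_env$mat
}
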