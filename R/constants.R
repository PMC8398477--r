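# Physical constants and residue tables used across the package.
# Monoisotopic residue masses follow the standard atomic masses
# (CODATA / IUPAC); modification deltas are the usual unimod values.

#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Monoisotopic residue masses (Da), i.e. amino acid minus water.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565
# Proton-neutral convention used in fragment ladders: hydrogen atomic mass
# minus the electron mass. Documented in the methods vignette.
MASS_PROTON <- 1.00794 - 0.00055

# Variable modification deltas (Da).
MOD_DELTA <- c(
  carbamidomethyl = 57.02146,  # +CH2CONH2 on Cys
  oxidation       = 15.99491,  # +O on Met
  pyroglu         = -17.02655, # N-terminal Gln -> pyroglutamate (loss of NH3)
  amide           = -0.98402   # C-terminal amidation (OH -> NH2)
)

# Kyte-Doolittle hydropathy index.
KYTE_DOOLITTLE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Residues accepted at the -1 and -3 positions of a signal peptidase site.
SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

# Version tag for the compiled-in constant tables, recorded in run manifests.
CONSTANTS_VERSION <- "nppipe-tables-1"

#' @keywords internal
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
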