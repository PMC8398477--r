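# Independent oracles used to check package computations. These are
# deliberately naive re-derivations (exhaustive DP, elemental composition,
# brute-force scans) kept separate from the implementation paths.

# Affine-gap Smith-Waterman score by explicit Gotoh recursion; a gap of
# length L costs open + ext * L.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Monoisotopic peptide mass from elemental composition and atomic masses
# (independent of the package's residue-mass table).
oracle_mass <- function(seq, carbamidomethyl = 0, oxidation = 0,
                        pyroglu = FALSE, amide = FALSE) {
  el <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
          O = 15.9949146196, S = 31.97207100)
  # residue formulas (amino acid minus water): C,H,N,O,S counts
  f <- list(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  comp <- c(0, 2, 0, 1, 0) # water
  for (r in strsplit(seq, "")[[1]]) comp <- comp + f[[r]]
  comp <- comp + carbamidomethyl * c(2, 3, 1, 1, 0) # +C2H3NO
  comp <- comp + oxidation * c(0, 0, 0, 1, 0)       # +O
  if (pyroglu) comp <- comp - c(0, 3, 1, 0, 0)      # -NH3
  if (amide) comp <- comp + c(0, 1, 1, -1, 0)       # -OH +NH2
  sum(comp * el)
}

# Nx by a brute-force descending scan.
oracle_nx <- function(lens, x) {
  lens <- sort(lens, decreasing = TRUE)
  tot <- sum(lens)
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= x / 100 * tot) return(l)
  }
}

# Average-linkage agglomeration by direct mean-pairwise-distance updates.
oracle_average_linkage_heights <- function(points) {
  d0 <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(points)))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# One-way ANOVA F by direct sums of squares.
oracle_anova_f <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); N <- length(all)
  (ssb / (k - 1)) / (ssw / (N - k))
}

random_protein <- function(n, alphabet = nppipe:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- nppipe:::blosum62_matrix()
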