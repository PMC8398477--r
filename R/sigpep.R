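#' Predict an N-terminal secretory signal peptide
#'
#' A transparent von Heijne-style heuristic. Candidate cleavage positions
#' 10-45 are scanned; each is scored from three components:
#' \describe{
#'   \item{h-score}{maximum mean Kyte-Doolittle hydropathy over any window
#'     of at least `h_window` residues inside residues `2..(c-3)`;}
#'   \item{n-score}{1 if at least one K/R occurs in residues 1-5, else 0.5;}
#'   \item{c-score}{1 if the residues at the -1 and -3 positions relative
#'     to the cleavage site are small (A, G, S, C, T), else 0.}
#' }
#' A position is a valid cleavage candidate when its c-score is 1 and its
#' h-score reaches `h_min`; the earliest valid position is reported as the
#' cleavage site (the c-region directly follows the hydrophobic core). The
#' reported presence score is the maximum per-position combined score
#' `n * min(h/4.5, 1) * c`, so it is monotone in each subscore.
#'
#' @param protein Protein sequence (character scalar).
#' @param h_min Minimum window hydropathy for a valid site (default 1.6).
#' @param h_window Minimum hydrophobic window length (default 8).
#' @param min_cleavage,max_cleavage Scanned cleavage range (10-45).
#' @return List of class `signal_prediction`: `present`, `cleavage_after`,
#'   `score`, `components` (n/h/c subscores at the reported site) and
#'   `reason` when absent.
#' @export
predict_signal_peptide <- function(protein, h_min = 1.6, h_window = 8L,
                                   min_cleavage = 10L, max_cleavage = 45L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n < 15L) {
    return(new_signal_prediction(FALSE, NA_integer_, 0,
                                 reason = "sequence shorter than 15 residues"))
  }
  aa <- strsplit(protein, "")[[1L]]
  kd <- unname(KYTE_DOOLITTLE[aa])
  kd[is.na(kd)] <- 0 # X and other unknowns contribute nothing
  n_score <- if (any(aa[1:5] %in% c("K", "R"))) 1 else 0.5

  cand <- seq.int(min_cleavage, min(max_cleavage, n - 1L))
  h_sc <- vapply(cand, function(cpos) max_window_mean(kd, 2L, cpos - 3L,
                                                      h_window), 0)
  c_sc <- vapply(cand, function(cpos) {
    as.numeric(aa[cpos] %in% SMALL_RESIDUES &&
                 aa[cpos - 2L] %in% SMALL_RESIDUES)
  }, 0)
  comb <- n_score * pmin(pmax(h_sc, 0) / 4.5, 1) * c_sc
  valid <- c_sc == 1 & h_sc >= h_min
  if (!any(valid)) {
    return(new_signal_prediction(FALSE, NA_integer_, max(comb, 0),
                                 reason = "no valid cleavage site"))
  }
  i <- which(valid)[[1L]]
  new_signal_prediction(TRUE, cand[[i]], max(comb),
                        components = c(n = n_score, h = h_sc[[i]],
                                       c = c_sc[[i]]))
}

# Max mean of kd[from..to] over all windows of length >= wmin.
#' @keywords internal
max_window_mean <- function(kd, from, to, wmin) {
  if (to - from + 1L < wmin) return(-Inf)
  v <- kd[from:to]
  cs <- c(0, cumsum(v))
  best <- -Inf
  nv <- length(v)
  for (w in wmin:nv) {
    sums <- cs[(w + 1L):(nv + 1L)] - cs[1L:(nv - w + 1L)]
    best <- max(best, max(sums) / w)
  }
  best
}

#' @keywords internal
new_signal_prediction <- function(present, cleavage_after, score,
                                  components = c(n = NA_real_, h = NA_real_,
                                                 c = NA_real_),
                                  reason = NULL) {
  structure(list(present = present, cleavage_after = cleavage_after,
                 score = score, components = components, reason = reason),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  if (x$present) {
    cat(sprintf("signal peptide: residues 1-%d (score %.3f)\n",
                x$cleavage_after, x$score))
  } else {
    cat(sprintf("no signal peptide (%s)\n", x$reason %||% "below threshold"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
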