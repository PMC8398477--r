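#' Monoisotopic neutral mass of a peptide with variable modifications
#'
#' Sum of residue monoisotopic masses plus one water, with modification
#' deltas: carbamidomethyl-Cys +57.02146 per site, Met oxidation
#' +15.99491 per site, N-terminal Gln pyroglutamate -17.02655 and
#' C-terminal amidation -0.98402.
#'
#' @param seq Peptide sequence (standard 20-letter alphabet).
#' @param carbamidomethyl,oxidation Number of modified Cys/Met residues.
#' @param pyroglu,amide Logical flags for the terminal modifications.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(seq, carbamidomethyl = 0L, oxidation = 0L,
                              pyroglu = FALSE, amide = FALSE) {
  seq <- toupper(seq)
  aa <- strsplit(seq, "")[[1L]]
  m <- RESIDUE_MASS[aa]
  if (anyNA(m)) stop("unknown residue: ", aa[which(is.na(m))[[1L]]])
  if (carbamidomethyl > sum(aa == "C"))
    stop("more carbamidomethyl sites than Cys residues")
  if (oxidation > sum(aa == "M"))
    stop("more oxidation sites than Met residues")
  if (pyroglu && aa[[1L]] != "Q")
    stop("pyroglutamate requires an N-terminal Gln")
  sum(m) + MASS_WATER +
    carbamidomethyl * MOD_DELTA[["carbamidomethyl"]] +
    oxidation * MOD_DELTA[["oxidation"]] +
    (if (pyroglu) MOD_DELTA[["pyroglu"]] else 0) +
    (if (amide) MOD_DELTA[["amide"]] else 0)
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical Neutral masses (Da); `theoretical > 0`.
#' @return Signed ppm error `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' b/y fragment ion ladder (neutral-plus-proton convention)
#'
#' `b_i` is the sum of the first `i` residue masses (with any
#' modifications placed there) plus the proton constant 1.00739;
#' `y_i` is the sum of the last `i` residue masses plus water plus the
#' proton constant. Side-chain modifications are placed on the first
#' `carbamidomethyl` Cys and first `oxidation` Met residues (N- to
#' C-terminal order); pyroglutamate sits on residue 1 and amidation on
#' the last residue. Under this convention
#' `b_i + y_(L-i) = neutral mass + 2 * 1.00739` exactly.
#'
#' @inheritParams monoisotopic_mass
#' @return List with numeric vectors `b` and `y` (lengths `L - 1`).
#' @export
fragment_ladder <- function(seq, carbamidomethyl = 0L, oxidation = 0L,
                            pyroglu = FALSE, amide = FALSE) {
  aa <- strsplit(toupper(seq), "")[[1L]]
  m <- unname(RESIDUE_MASS[aa])
  if (anyNA(m)) stop("unknown residue: ", aa[which(is.na(m))[[1L]]])
  if (carbamidomethyl > 0L) {
    idx <- which(aa == "C")[seq_len(carbamidomethyl)]
    m[idx] <- m[idx] + MOD_DELTA[["carbamidomethyl"]]
  }
  if (oxidation > 0L) {
    idx <- which(aa == "M")[seq_len(oxidation)]
    m[idx] <- m[idx] + MOD_DELTA[["oxidation"]]
  }
  if (pyroglu) m[[1L]] <- m[[1L]] + MOD_DELTA[["pyroglu"]]
  if (amide) m[[length(m)]] <- m[[length(m)]] + MOD_DELTA[["amide"]]
  L <- length(m)
  if (L < 2L) return(list(b = numeric(), y = numeric()))
  list(b = cumsum(m)[1:(L - 1L)] + MASS_PROTON,
       y = cumsum(rev(m))[1:(L - 1L)] + MASS_WATER + MASS_PROTON)
}

#' Build the peptide candidate list for mass matching
#'
#' In `mature` mode the candidates are the predicted mature peptides,
#' their partially processed (site-skipping) extended forms, and terminal
#' truncations with up to `max_trunc` residues trimmed from either end.
#' In `no_enzyme` mode every precursor substring with length in
#' `len_range` is a candidate. Each candidate is enumerated with all
#' allowed variable-modification combinations (carbamidomethyl-Cys, Met
#' oxidation, N-terminal Gln pyroglutamate where the sequence permits,
#' C-terminal amidation where predicted), capped at `max_mods`
#' modifications per peptide.
#'
#' @param annotations A `precursor_annotation` or list of them.
#' @param mode `"mature"` or `"no_enzyme"`.
#' @param len_range Candidate length range (default `c(4, 60)`).
#' @param max_mods Maximum modifications per candidate (default 3).
#' @param max_missed Maximum skipped sites for extended forms (default 1).
#' @param max_trunc Maximum residues trimmed per terminus (default 3).
#' @return data.frame: `candidate_id`, `precursor_id`, `seq`, `start`,
#'   `end`, `carbamidomethyl`, `oxidation`, `pyroglu`, `amide`, `mass`,
#'   `is_decoy`.
#' @export
build_candidates <- function(annotations, mode = c("mature", "no_enzyme"),
                             len_range = c(4L, 60L), max_mods = 3L,
                             max_missed = 1L, max_trunc = 3L) {
  mode <- match.arg(mode)
  if (length(len_range) != 2L || len_range[[1L]] < 1L ||
      len_range[[2L]] < len_range[[1L]])
    stop("invalid len_range")
  if (inherits(annotations, "precursor_annotation"))
    annotations <- list(annotations)
  base <- list()
  for (ann in annotations) {
    if (mode == "no_enzyme") {
      n <- nchar(ann$sequence)
      for (a in seq_len(n)) {
        if (n - a + 1L < len_range[[1L]]) break
        for (l in seq.int(len_range[[1L]], min(len_range[[2L]], n - a + 1L))) {
          base[[length(base) + 1L]] <- list(
            pid = ann$protein_id, seq = substr(ann$sequence, a, a + l - 1L),
            start = a, end = a + l - 1L, amid_ok = TRUE)
        }
      }
    } else {
      forms <- partially_processed_forms(ann, max_missed)
      peps <- ann$peptides
      if (nrow(peps)) {
        for (i in seq_len(nrow(peps))) {
          for (dn in 0:max_trunc) {
            for (dc in 0:max_trunc) {
              if (dn + dc == 0L) next
              a <- peps$start[[i]] + dn; b <- peps$end[[i]] - dc
              if (b - a + 1L < len_range[[1L]]) next
              forms <- rbind(forms, data.frame(
                seq = substr(ann$sequence, a, b), start = a, end = b,
                amidated = dc == 0L && peps$amidated[[i]],
                pyroglu = dn == 0L && peps$pyroglu[[i]],
                n_cys = 0L, evidence = "predicted",
                stringsAsFactors = FALSE))
            }
          }
        }
      }
      keep <- nchar(forms$seq) >= len_range[[1L]] &
        nchar(forms$seq) <= len_range[[2L]]
      forms <- forms[keep, , drop = FALSE]
      for (i in seq_len(nrow(forms))) {
        base[[length(base) + 1L]] <- list(
          pid = ann$protein_id, seq = forms$seq[[i]],
          start = forms$start[[i]], end = forms$end[[i]],
          amid_ok = forms$amidated[[i]])
      }
    }
  }
  rows <- lapply(base, function(b) enumerate_mods(b, max_mods))
  out <- do.call(rbind, c(list(empty_candidate_df()), rows))
  out <- out[!duplicated(out[, c("precursor_id", "seq", "start", "end",
                                 "carbamidomethyl", "oxidation", "pyroglu",
                                 "amide")]), , drop = FALSE]
  out$candidate_id <- sprintf(
    "%s:%d-%d:c%do%d%s%s", out$precursor_id, out$start, out$end,
    out$carbamidomethyl, out$oxidation,
    ifelse(out$pyroglu, "p", ""), ifelse(out$amide, "a", ""))
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_candidate_df <- function() {
  data.frame(candidate_id = character(), precursor_id = character(),
             seq = character(), start = integer(), end = integer(),
             carbamidomethyl = integer(), oxidation = integer(),
             pyroglu = logical(), amide = logical(), mass = numeric(),
             is_decoy = logical(), stringsAsFactors = FALSE)
}

#' @keywords internal
enumerate_mods <- function(b, max_mods) {
  aa <- strsplit(b$seq, "")[[1L]]
  nC <- sum(aa == "C"); nM <- sum(aa == "M")
  pg_opts <- if (aa[[1L]] == "Q") c(FALSE, TRUE) else FALSE
  am_opts <- if (isTRUE(b$amid_ok)) c(FALSE, TRUE) else FALSE
  grid <- expand.grid(carbamidomethyl = 0:nC, oxidation = 0:nM,
                      pyroglu = pg_opts, amide = am_opts)
  grid <- grid[grid$carbamidomethyl + grid$oxidation + grid$pyroglu +
                 grid$amide <= max_mods, , drop = FALSE]
  data.frame(candidate_id = "", precursor_id = b$pid, seq = b$seq,
             start = b$start, end = b$end,
             carbamidomethyl = grid$carbamidomethyl,
             oxidation = grid$oxidation, pyroglu = grid$pyroglu,
             amide = grid$amide,
             mass = mapply(monoisotopic_mass, seq = b$seq,
                           carbamidomethyl = grid$carbamidomethyl,
                           oxidation = grid$oxidation, pyroglu = grid$pyroglu,
                           amide = grid$amide, USE.NAMES = FALSE),
             is_decoy = FALSE, stringsAsFactors = FALSE)
}

#' Reverse-sequence decoy candidates
#'
#' Each candidate's sequence is reversed and its mass recomputed;
#' pyroglutamate is retained only when the reversed sequence still starts
#' with Gln.
#'
#' @param candidates data.frame from [build_candidates()].
#' @return data.frame of decoy candidates (`is_decoy = TRUE`).
#' @export
reverse_decoys <- function(candidates) {
  d <- candidates
  d$seq <- vapply(strsplit(d$seq, ""),
                  function(a) paste(rev(a), collapse = ""), "")
  d$pyroglu <- d$pyroglu & startsWith(d$seq, "Q")
  d$mass <- mapply(monoisotopic_mass, seq = d$seq,
                   carbamidomethyl = d$carbamidomethyl,
                   oxidation = d$oxidation, pyroglu = d$pyroglu,
                   amide = d$amide, USE.NAMES = FALSE)
  d$is_decoy <- TRUE
  d$candidate_id <- paste0("rev_", d$candidate_id)
  d <- d[!duplicated(d$candidate_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Match MS observations against a candidate list
#'
#' An observation matches every candidate whose theoretical neutral mass
#' lies within `ppm_tol` parts per million. When an observation carries
#' fragment masses, b/y ladders are computed for each candidate and the
#' number of theoretical ions matched within `frag_tol` Da is counted.
#' The score is `frag_matched / (2 * (len - 1)) - |ppm| / (10 * ppm_tol)`;
#' the best-scoring candidate per observation is flagged.
#'
#' @param observations data.frame with columns `source_id`, `obs_mass` and
#'   optionally `fragments` (semicolon-separated masses, Da).
#' @param candidates data.frame from [build_candidates()] (and/or
#'   [reverse_decoys()]).
#' @param ppm_tol Precursor tolerance in ppm (default 30).
#' @param frag_tol Fragment tolerance in Da (default 0.05).
#' @return data.frame of matches: observation and candidate fields,
#'   `ppm_error`, `frag_matched`, `frag_total`, `score`, `is_decoy`,
#'   `best`.
#' @export
match_peptides <- function(observations, candidates, ppm_tol = 30,
                           frag_tol = 0.05) {
  stopifnot(ppm_tol > 0, frag_tol > 0)
  empty <- data.frame(source_id = character(), candidate_id = character(),
                      precursor_id = character(), seq = character(),
                      obs_mass = numeric(), mass = numeric(),
                      carbamidomethyl = integer(), oxidation = integer(),
                      pyroglu = logical(), amide = logical(),
                      ppm_error = numeric(), frag_matched = integer(),
                      frag_total = integer(), score = numeric(),
                      is_decoy = logical(), best = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(observations) || !nrow(candidates)) return(empty)
  rows <- list(empty)
  has_frag <- "fragments" %in% names(observations)
  for (i in seq_len(nrow(observations))) {
    om <- observations$obs_mass[[i]]
    ppm <- ppm_error(om, candidates$mass)
    hit <- which(abs(ppm) <= ppm_tol)
    if (!length(hit)) next
    frags <- numeric()
    if (has_frag) {
      fr <- observations$fragments[[i]]
      if (!is.na(fr) && nzchar(fr))
        frags <- as.numeric(strsplit(fr, ";")[[1L]])
    }
    for (h in hit) {
      len <- nchar(candidates$seq[[h]])
      fm <- 0L; ft <- 2L * (len - 1L)
      if (length(frags) && len >= 2L) {
        lad <- fragment_ladder(candidates$seq[[h]],
                               candidates$carbamidomethyl[[h]],
                               candidates$oxidation[[h]],
                               candidates$pyroglu[[h]],
                               candidates$amide[[h]])
        theo <- c(lad$b, lad$y)
        fm <- sum(vapply(theo, function(t) any(abs(frags - t) <= frag_tol),
                         logical(1)))
      }
      frac <- if (ft > 0L) fm / ft else 0
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = observations$source_id[[i]],
        candidate_id = candidates$candidate_id[[h]],
        precursor_id = candidates$precursor_id[[h]],
        seq = candidates$seq[[h]], obs_mass = om,
        mass = candidates$mass[[h]],
        carbamidomethyl = candidates$carbamidomethyl[[h]],
        oxidation = candidates$oxidation[[h]],
        pyroglu = candidates$pyroglu[[h]], amide = candidates$amide[[h]],
        ppm_error = ppm[[h]], frag_matched = fm, frag_total = ft,
        score = frac - abs(ppm[[h]]) / (10 * ppm_tol),
        is_decoy = candidates$is_decoy[[h]], best = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  if (nrow(m)) {
    for (sid in unique(m$source_id)) {
      idx <- which(m$source_id == sid)
      ord <- idx[order(-m$score[idx], abs(m$ppm_error[idx]))]
      m$best[ord[[1L]]] <- TRUE
    }
  }
  rownames(m) <- NULL
  m
}

#' Target-decoy FDR filter
#'
#' Matches are ranked by score; the estimated FDR at a score cutoff is
#' the number of decoy matches at or above the cutoff divided by the
#' number of target matches at or above it (decoys rank first within
#' score ties, a conservative choice). Target matches whose monotonized
#' FDR (q-value) is at most `fdr_max` survive.
#'
#' @param matches Target matches (data.frame from [match_peptides()]).
#' @param decoy_matches Decoy matches (same layout).
#' @param fdr_max Maximum accepted FDR (default 0.001, i.e. 0.1 percent).
#' @return List: `matches` (surviving target matches), `threshold` (score
#'   cutoff; `Inf` when nothing survives), `n_decoys_above`.
#' @export
fdr_filter <- function(matches, decoy_matches, fdr_max = 0.001) {
  if (!nrow(matches))
    return(list(matches = matches, threshold = Inf, n_decoys_above = 0L))
  all <- rbind(
    data.frame(score = matches$score, decoy = FALSE, idx = seq_len(nrow(matches))),
    if (nrow(decoy_matches))
      data.frame(score = decoy_matches$score, decoy = TRUE, idx = NA_integer_)
  )
  ord <- order(-all$score, !all$decoy) # decoys first within ties
  all <- all[ord, , drop = FALSE]
  fdr <- cumsum(all$decoy) / pmax(cumsum(!all$decoy), 1L)
  qval <- rev(cummin(rev(fdr)))
  keep <- !all$decoy & qval <= fdr_max
  surv <- sort(all$idx[keep])
  thr <- if (length(surv)) min(all$score[keep]) else Inf
  list(matches = matches[surv, , drop = FALSE], threshold = thr,
       n_decoys_above = sum(all$decoy & all$score >= thr))
}
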