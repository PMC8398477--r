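#' Find prohormone convertase cleavage sites
#'
#' Every maximal run of two or more K/R residues yields one site
#' (`dibasic` for runs of length 2, `multibasic` for longer runs) whose
#' `position` is the run's last residue; runs are never split into
#' overlapping sites. Isolated single K/R residues are reported as
#' `monobasic` sites when `include_monobasic = TRUE`.
#'
#' @param propeptide Protein sequence (the precursor minus its signal
#'   peptide). Positions are 1-based on this sequence.
#' @param include_monobasic Also report isolated single K/R (default
#'   `FALSE`).
#' @return data.frame with columns `position`, `kind`, `motif`.
#' @export
find_cleavage_sites <- function(propeptide, include_monobasic = FALSE) {
  propeptide <- toupper(propeptide)
  m <- gregexpr("[KR]+", propeptide)[[1L]]
  out <- data.frame(position = integer(), kind = character(),
                    motif = character(), stringsAsFactors = FALSE)
  if (m[[1L]] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= 2L | include_monobasic
  starts <- starts[keep]; lens <- lens[keep]
  if (!length(starts)) return(out)
  data.frame(
    position = starts + lens - 1L,
    kind = ifelse(lens == 1L, "monobasic",
                  ifelse(lens == 2L, "dibasic", "multibasic")),
    motif = substring(propeptide, starts, starts + lens - 1L),
    stringsAsFactors = FALSE)
}

#' Derive mature peptides from a precursor and its cleavage sites
#'
#' Peptides are the segments between the signal peptide end, the cut
#' sites, and the C-terminus, with the basic residues of each cut site
#' excluded. A segment of two or more residues ending in glycine and
#' followed by a cut site loses that sacrificial glycine and is flagged
#' `amidated`; the same applies to the C-terminal segment only when
#' `allow_terminal_amide = TRUE`. A segment starting with glutamine is
#' flagged `pyroglu` when `pyroglu = TRUE` (the sequence is unchanged;
#' the mass difference is applied downstream). Empty segments (adjacent
#' sites) are dropped.
#'
#' @param precursor Full precursor protein sequence.
#' @param signal_end Last residue of the signal peptide (0 if none).
#' @param sites data.frame as from [find_cleavage_sites()], with
#'   `position` in precursor coordinates; only rows whose `kind` is
#'   dibasic/multibasic (plus monobasic when `cut_monobasic = TRUE`) cut.
#' @param pyroglu Annotate N-terminal Gln cyclization (default `TRUE`).
#' @param allow_terminal_amide Permit amidation of the C-terminal peptide
#'   (default `FALSE`; no downstream basic site exists at the terminus).
#' @param cut_monobasic Also cut at monobasic sites (default `FALSE`).
#' @return data.frame with columns `seq`, `start`, `end` (1-based span of
#'   the trimmed peptide in the precursor), `amidated`, `pyroglu`,
#'   `n_cys`, `evidence`.
#' @export
derive_peptides <- function(precursor, signal_end, sites,
                            pyroglu = TRUE, allow_terminal_amide = FALSE,
                            cut_monobasic = FALSE) {
  precursor <- toupper(precursor)
  n <- nchar(precursor)
  cuts <- sites[sites$kind %in% c("dibasic", "multibasic") |
                  (cut_monobasic & sites$kind == "monobasic"), , drop = FALSE]
  if (anyDuplicated(cuts$position)) stop("duplicate cleavage sites")
  cuts <- cuts[order(cuts$position), , drop = FALSE]
  motif_start <- cuts$position - nchar(cuts$motif) + 1L
  if (any(motif_start[-1L] <= cuts$position[-nrow(cuts)]) ||
      any(motif_start <= signal_end))
    stop("overlapping cleavage sites")
  seg_start <- c(signal_end + 1L, cuts$position + 1L)
  seg_end <- c(motif_start - 1L, n)
  followed <- c(rep(TRUE, nrow(cuts)), FALSE)
  peps <- list(empty_peptide_df())
  for (i in seq_along(seg_start)) {
    a <- seg_start[[i]]; b <- seg_end[[i]]
    if (b < a) next
    amid <- FALSE
    if ((followed[[i]] || allow_terminal_amide) && b - a + 1L >= 2L &&
        substr(precursor, b, b) == "G") {
      amid <- TRUE
      b <- b - 1L
    }
    sq <- substr(precursor, a, b)
    peps[[length(peps) + 1L]] <- data.frame(
      seq = sq, start = a, end = b, amidated = amid,
      pyroglu = pyroglu && startsWith(sq, "Q"),
      n_cys = lengths(regmatches(sq, gregexpr("C", sq))),
      evidence = "predicted", stringsAsFactors = FALSE)
  }
  do.call(rbind, peps)
}

#' @keywords internal
empty_peptide_df <- function() {
  data.frame(seq = character(), start = integer(), end = integer(),
             amidated = logical(), pyroglu = logical(), n_cys = integer(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' Annotate a precursor protein end to end
#'
#' Runs signal-peptide prediction, cleavage-site discovery and mature
#' peptide derivation, and verifies the reconstruction invariant: the
#' signal peptide, peptide bodies, sacrificial glycines and cut-site
#' motifs concatenate back to the precursor exactly.
#'
#' @param protein Precursor protein sequence.
#' @param id Identifier stored in the annotation.
#' @param include_monobasic Report monobasic sites (annotate-only unless
#'   `cut_monobasic`).
#' @param cut_monobasic Cut at monobasic sites (default `FALSE`).
#' @param pyroglu,allow_terminal_amide Passed to [derive_peptides()].
#' @param strict Error when no signal peptide is predicted (default);
#'   otherwise treat residue 1 as the propeptide start with a warning.
#' @return List of class `precursor_annotation`: `protein_id`, `sequence`,
#'   `signal`, `sites` (precursor coordinates, with a `cut` flag),
#'   `peptides`.
#' @export
annotate_precursor <- function(protein, id = "precursor",
                               include_monobasic = TRUE,
                               cut_monobasic = FALSE, pyroglu = TRUE,
                               allow_terminal_amide = FALSE, strict = TRUE) {
  protein <- toupper(protein)
  sig <- predict_signal_peptide(protein)
  if (!sig$present) {
    if (strict) stop("no signal peptide predicted for ", id,
                     " (", sig$reason %||% "below threshold", ")")
    warning("no signal peptide for ", id,
            "; treating residue 1 as propeptide start")
  }
  sig_end <- if (sig$present) sig$cleavage_after else 0L
  prop <- substr(protein, sig_end + 1L, nchar(protein))
  sites <- find_cleavage_sites(prop, include_monobasic = include_monobasic)
  if (nrow(sites)) sites$position <- sites$position + sig_end
  sites$cut <- sites$kind %in% c("dibasic", "multibasic") |
    (cut_monobasic & sites$kind == "monobasic")
  peptides <- derive_peptides(protein, sig_end, sites, pyroglu = pyroglu,
                              allow_terminal_amide = allow_terminal_amide,
                              cut_monobasic = cut_monobasic)
  ann <- structure(list(protein_id = id, sequence = protein, signal = sig,
                        sites = sites, peptides = peptides),
                   class = "precursor_annotation")
  if (!check_reconstruction(ann))
    stop("internal error: reconstruction invariant violated for ", id)
  ann
}

#' Verify the precursor reconstruction invariant
#'
#' Rebuilds the precursor from its parts alone (signal sequence, peptide
#' bodies, sacrificial glycines, cut-site motifs) and compares with the
#' stored sequence.
#'
#' @param ann A `precursor_annotation`.
#' @return `TRUE` when the concatenation reproduces the precursor exactly.
#' @export
check_reconstruction <- function(ann) {
  sig_end <- if (ann$signal$present) ann$signal$cleavage_after else 0L
  parts <- data.frame(start = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (sig_end > 0L)
    parts <- rbind(parts, data.frame(
      start = 1L, text = substr(ann$sequence, 1L, sig_end)))
  p <- ann$peptides
  if (nrow(p))
    parts <- rbind(parts, data.frame(
      start = p$start,
      text = paste0(p$seq, ifelse(p$amidated, "G", ""))))
  s <- ann$sites[ann$sites$cut, , drop = FALSE]
  if (nrow(s))
    parts <- rbind(parts, data.frame(
      start = s$position - nchar(s$motif) + 1L, text = s$motif))
  rebuilt <- paste(parts$text[order(parts$start)], collapse = "")
  identical(rebuilt, ann$sequence)
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat(sprintf("precursor %s (%d aa): signal 1-%s, %d site(s), %d peptide(s)\n",
              x$protein_id, nchar(x$sequence),
              if (x$signal$present) x$signal$cleavage_after else "none",
              nrow(x$sites), nrow(x$peptides)))
  if (nrow(x$peptides)) {
    lab <- paste0(ifelse(x$peptides$pyroglu, "pyroGlu-", ""),
                  x$peptides$seq,
                  ifelse(x$peptides$amidated, "-amide", ""))
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Enumerate partially processed peptide forms
#'
#' Extended forms arise when convertase processing skips sites; every
#' contiguous merge of adjacent peptides spanning at most
#' `max_missed_sites` uncleaved sites is enumerated, with the intervening
#' basic residues (and internal sacrificial glycines) retained in the
#' sequence. Amidation can only apply at the final boundary and
#' pyroglutamate at the first.
#'
#' @param ann A `precursor_annotation`.
#' @param max_missed_sites Maximum number of skipped cut sites (default 1).
#' @return data.frame in the [derive_peptides()] layout (includes the
#'   fully processed singleton forms).
#' @export
partially_processed_forms <- function(ann, max_missed_sites = 1L) {
  p <- ann$peptides
  if (!nrow(p)) return(p)
  out <- list(empty_peptide_df())
  for (i in seq_len(nrow(p))) {
    for (j in i:min(nrow(p), i + max_missed_sites)) {
      sq <- substr(ann$sequence, p$start[[i]], p$end[[j]])
      out[[length(out) + 1L]] <- data.frame(
        seq = sq, start = p$start[[i]], end = p$end[[j]],
        amidated = p$amidated[[j]], pyroglu = p$pyroglu[[i]],
        n_cys = lengths(regmatches(sq, gregexpr("C", sq))),
        evidence = "predicted", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
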