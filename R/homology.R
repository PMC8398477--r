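#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' BLOSUM62 scoring with affine gap penalties in the BLAST convention
#' (a gap of length L costs `gap_open + gap_extend * L`).
#'
#' @param query,target Protein sequences (character scalars).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11, 1).
#' @return List of class `alignment_result`: `score`, `identity_pct`,
#'   `similarity_pct`, `align_length`, `query_span`, `target_span`.
#' @export
align_local <- function(query, target, gap_open = 11, gap_extend = 1) {
  query <- toupper(query); target <- toupper(target)
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  mat <- blosum62_matrix()
  for (s in c(query, target)) {
    bad <- setdiff(strsplit(s, "")[[1L]], rownames(mat))
    if (length(bad))
      stop("residue not in substitution matrix alphabet: ", bad[[1L]])
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(structure(list(score = 0, identity_pct = 0, similarity_pct = 0,
                          align_length = 0L,
                          query_span = c(NA_integer_, NA_integer_),
                          target_span = c(NA_integer_, NA_integer_)),
                     class = "alignment_result"))
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  len <- length(ap)
  aligned <- ap != "-" & as_ != "-"
  matches <- sum(aligned & ap == as_)
  pos <- sum(vapply(which(aligned), function(i) mat[ap[i], as_[i]] > 0,
                    logical(1)))
  pr <- al@pattern@range
  sr <- al@subject@range
  structure(list(
    score = sc,
    identity_pct = 100 * matches / len,
    similarity_pct = 100 * pos / len,
    align_length = len,
    query_span = c(pr@start, pr@start + pr@width - 1L),
    target_span = c(sr@start, sr@start + sr@width - 1L)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "local alignment: score %.1f, %.1f%% identity, %.1f%% similarity over %d columns\n",
    x$score, x$identity_pct, x$similarity_pct, x$align_length))
  invisible(x)
}

#' Karlin-Altschul E-value (ungapped-style approximation)
#'
#' `E = K * m * n * exp(-lambda * score)` with `m` the query length and
#' `n` the summed target database length. Defaults are the published
#' ungapped BLOSUM62 constants.
#'
#' @param score Alignment score.
#' @param query_len,target_db_len Search-space dimensions (> 0).
#' @param K,lambda Karlin-Altschul constants.
#' @return Expected number of chance hits (numeric).
#' @export
evalue <- function(score, query_len, target_db_len, K = 0.041,
                   lambda = 0.267) {
  stopifnot(score >= 0, query_len > 0, target_db_len > 0)
  K * query_len * target_db_len * exp(-lambda * score)
}

#' Screen candidate proteins against a panel of known NPP queries
#'
#' A target is accepted when its minimum E-value over the query panel is
#' at most `e_max` and it displays the features of a neuropeptide
#' precursor: a predicted signal peptide, at least one potential
#' convertase cleavage site in the propeptide, and a length within
#' `len_max` residues. The length criterion is a soft filter by default:
#' a target exceeding `len_max` is still kept when its homology is very
#' strong (E below `e_max / 100`), since large well-conserved precursors
#' are otherwise lost.
#'
#' @param queries,targets Named character vectors of protein sequences.
#' @param e_max E-value acceptance threshold (default 1.3).
#' @param len_max Maximum precursor length (default 150).
#' @param require_signal,require_sites Toggle the feature requirements.
#' @param length_mode `"soft"` (homology override), `"hard"` or `"off"`.
#' @param K,lambda Karlin-Altschul constants passed to [evalue()].
#' @return data.frame with one row per target: `target_id`, `accepted`,
#'   `evalue`, `best_query`, `score`, feature flags, and a comma-separated
#'   `reasons` field listing every failed criterion.
#' @export
screen_candidates <- function(queries, targets, e_max = 1.3, len_max = 150L,
                              require_signal = TRUE, require_sites = TRUE,
                              length_mode = c("soft", "hard", "off"),
                              K = 0.041, lambda = 0.267) {
  length_mode <- match.arg(length_mode)
  stopifnot(length(queries) > 0, length(targets) > 0)
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  db_len <- sum(nchar(targets))
  qset <- Biostrings::AAStringSet(toupper(unname(queries)))
  qnames <- names(queries) %||% as.character(seq_along(queries))
  qlens <- nchar(queries)
  mat <- blosum62_matrix()
  rows <- lapply(names(targets), function(tid) {
    tgt <- targets[[tid]]
    scores <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(toupper(tgt)), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    evs <- evalue(pmax(scores, 0), qlens, db_len, K, lambda)
    i <- which.min(evs)
    best_e <- evs[[i]]; best_q <- qnames[[i]]; best_s <- max(scores[[i]], 0)
    sig <- predict_signal_peptide(tgt)
    prop <- if (sig$present) substr(tgt, sig$cleavage_after + 1L, nchar(tgt))
            else tgt
    n_sites <- nrow(find_cleavage_sites(prop, include_monobasic = TRUE))
    e_ok <- best_e <= e_max
    sig_ok <- !require_signal || sig$present
    sites_ok <- !require_sites || n_sites >= 1L
    len_ok <- switch(length_mode,
      off  = TRUE,
      hard = nchar(tgt) <= len_max,
      soft = nchar(tgt) <= len_max || best_e <= e_max / 100)
    reasons <- c("evalue", "signal_peptide", "cleavage_sites", "length")[
      !c(e_ok, sig_ok, sites_ok, len_ok)]
    data.frame(target_id = tid, accepted = e_ok && sig_ok && sites_ok && len_ok,
               evalue = best_e, best_query = best_q, score = best_s,
               signal_peptide = sig$present, n_sites = n_sites,
               length = nchar(tgt),
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
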