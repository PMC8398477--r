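#' Find open reading frames in all six frames
#'
#' Reports all maximal stop-to-stop translations (or ATG-to-stop when
#' `require_start = TRUE`, i.e. from the first ATG of each stop-free
#' stretch) of at least `min_len_aa` residues, using the standard genetic
#' code. The terminal stop is not included in the protein. Ambiguous
#' codons translate to `X` where they cannot be resolved.
#'
#' @param seq DNA sequence (character scalar).
#' @param id Contig identifier recorded in the output.
#' @param min_len_aa Minimum protein length (default 60).
#' @param require_start Require an initiating ATG (default `FALSE`).
#' @return data.frame with columns `contig_id`, `frame` (+1,+2,+3,-1,-2,-3),
#'   `nt_start`, `nt_end` (1-based inclusive on the forward strand, stop
#'   codon excluded) and `protein`.
#' @export
find_orfs <- function(seq, id = "contig", min_len_aa = 60L,
                      require_start = FALSE) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  L <- nchar(seq)
  out <- list(empty_orf_df())
  if (L >= 3L) {
    for (strand in c(1L, -1L)) {
      work <- if (strand == 1L) seq else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      for (f in 0:2) {
        ncod <- (L - f) %/% 3L
        if (ncod < 1L) next
        sub <- substr(work, f + 1L, f + 3L * ncod)
        prot <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(sub), if.fuzzy.codon = "solve")))
        out[[length(out) + 1L]] <-
          frame_orfs(prot, f, strand, L, id, min_len_aa, require_start)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$nt_start, res$nt_end, res$frame), , drop = FALSE]
}

#' @keywords internal
empty_orf_df <- function() {
  data.frame(contig_id = character(), frame = integer(),
             nt_start = integer(), nt_end = integer(),
             protein = character(), stringsAsFactors = FALSE)
}

# Extract ORFs from one translated frame. f is the 0-based frame offset on
# the working (already strand-oriented) sequence.
#' @keywords internal
frame_orfs <- function(prot, f, strand, L, id, min_len_aa, require_start) {
  aa <- strsplit(prot, "")[[1L]]
  stops <- c(0L, which(aa == "*"), length(aa) + 1L)
  rows <- list(empty_orf_df())
  for (k in seq_len(length(stops) - 1L)) {
    a <- stops[[k]] + 1L
    b <- stops[[k + 1L]] - 1L
    if (b < a) next
    if (require_start) {
      ms <- which(aa[a:b] == "M")
      if (!length(ms)) next
      a <- a + ms[[1L]] - 1L
    }
    if (b - a + 1L < min_len_aa) next
    w1 <- f + 3L * (a - 1L) + 1L
    w2 <- f + 3L * b
    if (strand == 1L) {
      s1 <- w1; s2 <- w2
    } else {
      s1 <- L - w2 + 1L; s2 <- L - w1 + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = id, frame = strand * (f + 1L),
      nt_start = s1, nt_end = s2,
      protein = paste(aa[a:b], collapse = ""), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
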