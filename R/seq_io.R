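#' Read a FASTA file into a named character vector
#'
#' Sequences are whitespace-stripped, uppercased and validated against the
#' IUPAC alphabet for the stated molecule type (ambiguity codes are allowed
#' for DNA; `X` is allowed for protein).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return Named character vector of sequences (names are record ids, in
#'   file order) with attribute `moltype`.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1L]])
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  names(seqs) <- ids
  for (i in seq_along(seqs)) validate_seq(seqs[[i]], moltype, ids[[i]])
  attr(seqs, "moltype") <- moltype
  seqs
}

#' @keywords internal
validate_seq <- function(seq, moltype, id = "<seq>") {
  if (!nzchar(seq)) stop("empty sequence for record ", id)
  legal <- if (moltype == "dna") {
    "ACGTUryswkmbdhvnRYSWKMBDHVN" # IUPAC nucleotide incl. ambiguity
  } else {
    paste0(paste(AA20, collapse = ""), "X")
  }
  bad <- regexpr(sprintf("[^%s]", legal), seq)
  if (bad > 0L) {
    stop(sprintf("illegal %s character '%s' at position %d in record %s",
                 moltype, substr(seq, bad, bad), bad, id))
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file (60-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) stop("no records to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all records must be named")
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path, width = 60L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write FASTA to ", path)
  invisible(path)
}

#' Assembly summary statistics (N50/N90)
#'
#' `Nx` is the length of the smallest contig in the minimal
#' descending-length prefix whose cumulative length reaches x percent of
#' the total assembly size.
#'
#' @param x Named character vector of sequences, or a numeric vector of
#'   contig lengths.
#' @return A list of class `contig_stats` with `n_contigs`, `total_bases`,
#'   `n50` and `n90`.
#' @export
contig_stats <- function(x) {
  lens <- if (is.character(x)) nchar(x) else as.numeric(x)
  if (length(lens) == 0L) stop("no contigs")
  if (any(lens <= 0)) stop("contig lengths must be positive")
  structure(
    list(n_contigs = length(lens), total_bases = sum(lens),
         n50 = nx_length(lens, 50), n90 = nx_length(lens, 90)),
    class = "contig_stats")
}

#' @keywords internal
nx_length <- function(lens, x) {
  lens <- sort(lens, decreasing = TRUE)
  lens[[which(cumsum(lens) >= x / 100 * sum(lens))[[1L]]]]
}

#' @export
print.contig_stats <- function(x, ...) {
  cat(sprintf("%d contigs, %d bases total; N50 = %d, N90 = %d\n",
              x$n_contigs, x$total_bases, x$n50, x$n90))
  invisible(x)
}

#' Write an annotation table for one or more precursor annotations
#'
#' One row per feature (signal peptide, cleavage site, mature peptide),
#' with 1-based inclusive coordinates on the precursor protein.
#'
#' @param annotations A `precursor_annotation` or list of them.
#' @param path Output path (tab-separated).
#' @return The table, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  if (inherits(annotations, "precursor_annotation"))
    annotations <- list(annotations)
  rows <- lapply(annotations, annotation_rows)
  tab <- do.call(rbind, c(list(annotation_rows(NULL)), rows))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' @keywords internal
annotation_rows <- function(ann) {
  empty <- data.frame(precursor_id = character(), feature_type = character(),
                      start = integer(), end = integer(),
                      sequence = character(), modifications = character(),
                      stringsAsFactors = FALSE)
  if (is.null(ann)) return(empty)
  rows <- list(empty)
  if (isTRUE(ann$signal$present)) {
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = ann$protein_id, feature_type = "signal_peptide",
      start = 1L, end = ann$signal$cleavage_after,
      sequence = substr(ann$sequence, 1L, ann$signal$cleavage_after),
      modifications = "", stringsAsFactors = FALSE)
  }
  if (nrow(ann$sites)) {
    s <- ann$sites
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = ann$protein_id,
      feature_type = paste0("cleavage_site_", s$kind),
      start = s$position - nchar(s$motif) + 1L, end = s$position,
      sequence = s$motif, modifications = "", stringsAsFactors = FALSE)
  }
  if (nrow(ann$peptides)) {
    p <- ann$peptides
    mods <- mapply(function(a, q) {
      paste(c(if (q) "pyroGlu" else NULL, if (a) "amide" else NULL),
            collapse = ";")
    }, p$amidated, p$pyroglu)
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = ann$protein_id, feature_type = "mature_peptide",
      start = p$start, end = p$end, sequence = p$seq,
      modifications = as.character(mods), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
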