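# Ground-truthed generators for every pipeline stage. Defaults emulate the
# study conditions: 26 expression pools over four gametogenesis stages, a
# 96-transcript NPP panel with 25 stage-differential members, 30-ppm-scale
# mass accuracy, and precursors with signal peptides, basic cleavage sites
# and amidation/pyroGlu-competent peptides.

#' Generate a synthetic neuropeptide precursor with known truth
#'
#' The precursor is a signal peptide (Met + 1-2 basic n-region residues +
#' a hydrophobic h-region + a c-region ending in small residues at the
#' -1 and -3 positions) followed by peptide bodies separated by basic
#' cleavage sites. Amidated peptides carry a sacrificial Gly immediately
#' before their site; pyroGlu-competent peptides start with Gln; all
#' other bodies avoid those terminal residues so the processing truth is
#' unambiguous. The terminal peptide is never amidated (no downstream
#' site exists to donate from).
#'
#' @param n_peptides Number of mature peptides (>= 1).
#' @param peptide_len Length range of peptide bodies (default 6-12).
#' @param p_amidated,p_pyroglu,p_monobasic Per-peptide/site probabilities.
#' @param h_len,c_len Signal h-region length range and c-region length.
#' @param id Record identifier.
#' @param seed Optional RNG seed (reproducible output).
#' @return List of class `precursor_truth`: `id`, `sequence`,
#'   `signal_end`, `sites` (precursor coordinates), `peptides`.
#' @export
gen_precursor <- function(n_peptides = 3L, peptide_len = c(6L, 12L),
                          p_amidated = 0.5, p_pyroglu = 0.2,
                          p_monobasic = 0, h_len = c(8L, 12L), c_len = 4L,
                          id = "prec1", seed = NULL) {
  stopifnot(n_peptides >= 1L, p_amidated >= 0, p_amidated <= 1,
            p_pyroglu >= 0, p_pyroglu <= 1, p_monobasic >= 0,
            p_monobasic <= 1, peptide_len[[1L]] >= 2L,
            h_len[[1L]] >= 8L, c_len >= 4L)
  if (!is.null(seed)) set.seed(seed)
  hydro <- c("L", "I", "V", "F", "M")   # no Ala: keeps -1/-3 rule unique
  small <- c("A", "S", "T")
  nonsmall <- c("H", "N", "Q", "E", "D", "P")
  body_pool <- setdiff(AA20, c("K", "R"))

  sig <- c("M", sample(c("K", "R"), sample(1:2, 1L), replace = TRUE),
           sample(hydro, sample(h_len[[1L]]:h_len[[2L]], 1L), replace = TRUE))
  creg <- character(c_len)
  for (i in seq_len(c_len)) { # alternate non-small/small, small at -1/-3
    creg[[i]] <- if ((c_len - i) %% 2L == 0L) sample(small, 1L)
                 else sample(nonsmall, 1L)
  }
  sig <- c(sig, creg)
  signal_end <- length(sig)

  seq_parts <- paste(sig, collapse = "")
  pos <- signal_end
  peptides <- list()
  sites <- list()
  for (i in seq_len(n_peptides)) {
    len <- sample(peptide_len[[1L]]:peptide_len[[2L]], 1L)
    amid <- i < n_peptides && stats::runif(1) < p_amidated
    pg <- stats::runif(1) < p_pyroglu
    body <- sample(body_pool, len, replace = TRUE)
    body[[1L]] <- if (pg) "Q" else sample(setdiff(body_pool, "Q"), 1L)
    body[[len]] <- sample(setdiff(body_pool, "G"), 1L)
    peptides[[i]] <- data.frame(
      start = pos + 1L, end = pos + len,
      seq = paste(body, collapse = ""), amidated = amid, pyroglu = pg,
      stringsAsFactors = FALSE)
    consumed <- paste0(paste(body, collapse = ""), if (amid) "G" else "")
    seq_parts <- paste0(seq_parts, consumed)
    pos <- pos + nchar(consumed)
    if (i < n_peptides) {
      mono <- stats::runif(1) < p_monobasic
      motif <- if (mono) sample(c("K", "R"), 1L)
               else sample(c("KR", "RR", "KK", "RK"), 1L)
      sites[[length(sites) + 1L]] <- data.frame(
        position = pos + nchar(motif),
        kind = if (mono) "monobasic" else "dibasic", motif = motif,
        stringsAsFactors = FALSE)
      seq_parts <- paste0(seq_parts, motif)
      pos <- pos + nchar(motif)
    }
  }
  structure(list(
    id = id, sequence = seq_parts, signal_end = signal_end,
    sites = if (length(sites)) do.call(rbind, sites) else
      data.frame(position = integer(), kind = character(),
                 motif = character(), stringsAsFactors = FALSE),
    peptides = do.call(rbind, peptides)),
    class = "precursor_truth")
}

#' Convert a precursor truth into a `precursor_annotation`
#'
#' Builds the annotation object the prohormone module would produce on
#' perfect recovery (all truth sites treated as cut). Useful for
#' constructing candidate lists directly from truth.
#'
#' @param truth A `precursor_truth`.
#' @return A `precursor_annotation`.
#' @export
truth_annotation <- function(truth) {
  p <- truth$peptides
  sites <- truth$sites
  sites$cut <- rep(TRUE, nrow(sites))
  ann <- structure(list(
    protein_id = truth$id, sequence = truth$sequence,
    signal = new_signal_prediction(TRUE, truth$signal_end, 1,
                                   components = c(n = 1, h = NA, c = 1)),
    sites = sites,
    peptides = data.frame(
      seq = p$seq, start = p$start, end = p$end, amidated = p$amidated,
      pyroglu = p$pyroglu,
      n_cys = lengths(regmatches(p$seq, gregexpr("C", p$seq))),
      evidence = "predicted", stringsAsFactors = FALSE)),
    class = "precursor_annotation")
  stopifnot(check_reconstruction(ann))
  ann
}

#' Generate transcript contigs encoding precursor truths
#'
#' Reverse-translates each precursor with uniformly sampled synonymous
#' codons, appends a stop codon and random UTRs, and places the CDS on a
#' random strand. The last three bases of the 5' UTR are an in-frame TAA
#' so the maximal ATG-to-stop reading frame starts at the true start
#' codon.
#'
#' @param truths List of `precursor_truth` objects (or one).
#' @param utr_len UTR length on each side (0 or >= 3; default 30).
#' @param seed Optional RNG seed.
#' @return List: `records` (named character vector of DNA sequences),
#'   `info` (data.frame with `id`, `strand`).
#' @export
gen_transcripts <- function(truths, utr_len = 30L, seed = NULL) {
  if (inherits(truths, "precursor_truth")) truths <- list(truths)
  stopifnot(length(truths) > 0, utr_len == 0L || utr_len >= 3L)
  if (!is.null(seed)) set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  recs <- character(length(truths))
  info <- data.frame(id = character(length(truths)),
                     strand = character(length(truths)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    aa <- strsplit(tr$sequence, "")[[1L]]
    codons <- vapply(aa, function(a) {
      opts <- by_aa[[a]]
      opts[[sample.int(length(opts), 1L)]]
    }, "")
    cds <- paste0(paste(codons, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    utr5 <- rand_dna(utr_len)
    if (utr_len >= 3L) substr(utr5, utr_len - 2L, utr_len) <- "TAA"
    utr3 <- rand_dna(utr_len)
    tx <- paste0(utr5, cds, utr3)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      tx <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tx)))
    }
    recs[[i]] <- tx
    info$id[[i]] <- tr$id
    info$strand[[i]] <- strand
  }
  names(recs) <- info$id
  list(records = recs, info = info)
}

#' @keywords internal
rand_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic MS observations from precursor truths
#'
#' For each truth peptide (length >= 4), the observed neutral mass is the
#' theoretical mass of its (possibly modified) form multiplied by
#' `1 + e`, `e ~ Normal(0, ppm_sd * 1e-6)`. The predicted amidation state
#' is applied as-is; with probability `p_modified` one additional
#' applicable modification (carbamidomethyl, oxidation or pyroGlu) is
#' sampled. Optional b/y fragment lists carry Normal(0, `frag_sd`) Da
#' noise. Decoy observations are rejection-sampled to lie more than 200
#' ppm from every mature-mode candidate mass derivable from the truths
#' (peptides, extended forms, truncations, all modification combinations),
#' so a correctly tolerant matcher can never match them.
#'
#' @param truths List of `precursor_truth` objects (or one).
#' @param ppm_sd Relative mass noise in ppm (default 8).
#' @param p_modified Probability of one extra variable modification.
#' @param n_decoys Number of decoy observations.
#' @param with_fragments Attach noisy b/y fragment lists.
#' @param frag_sd Fragment mass noise in Da (default 0.01).
#' @param seed Optional RNG seed.
#' @return data.frame: `source_id`, `obs_mass`, `fragments`
#'   (semicolon-separated or `NA`), `is_decoy`, and truth columns
#'   (`true_precursor`, `true_seq`, `true_carbamidomethyl`,
#'   `true_oxidation`, `true_pyroglu`, `true_amide`).
#' @export
gen_ms_observations <- function(truths, ppm_sd = 8, p_modified = 0.3,
                                n_decoys = 0L, with_fragments = FALSE,
                                frag_sd = 0.01, seed = NULL) {
  if (inherits(truths, "precursor_truth")) truths <- list(truths)
  stopifnot(ppm_sd >= 0, n_decoys >= 0L)
  if (!is.null(seed)) set.seed(seed)
  anns <- lapply(truths, truth_annotation)
  rows <- list()
  for (ann in anns) {
    p <- ann$peptides[nchar(ann$peptides$seq) >= 4L, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      sq <- p$seq[[i]]
      carb <- 0L; ox <- 0L; pg <- FALSE
      if (stats::runif(1) < p_modified) {
        opts <- c(if (grepl("C", sq)) "carb",
                  if (grepl("M", sq)) "ox",
                  if (p$pyroglu[[i]]) "pg")
        if (length(opts)) {
          pick <- opts[[sample.int(length(opts), 1L)]]
          if (pick == "carb") carb <- 1L
          if (pick == "ox") ox <- 1L
          if (pick == "pg") pg <- TRUE
        }
      }
      am <- p$amidated[[i]]
      theo <- monoisotopic_mass(sq, carb, ox, pg, am)
      obs <- theo * (1 + stats::rnorm(1, 0, ppm_sd * 1e-6))
      frags <- NA_character_
      if (with_fragments) {
        lad <- fragment_ladder(sq, carb, ox, pg, am)
        f <- c(lad$b, lad$y) + stats::rnorm(2L * (nchar(sq) - 1L), 0, frag_sd)
        frags <- paste(sprintf("%.5f", f), collapse = ";")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sprintf("%s_pep%d", ann$protein_id, i), obs_mass = obs,
        fragments = frags, is_decoy = FALSE, true_precursor = ann$protein_id,
        true_seq = sq, true_carbamidomethyl = carb, true_oxidation = ox,
        true_pyroglu = pg, true_amide = am, stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0L) {
    avoid <- sort(build_candidates(anns, mode = "mature")$mass)
    lo <- max(min(avoid) * 0.8, 300); hi <- max(avoid) * 1.2
    made <- 0L
    while (made < n_decoys) {
      m <- stats::runif(1, lo, hi)
      if (any(abs(m / avoid - 1) <= 200e-6)) next
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sprintf("decoy_%d", made), obs_mass = m,
        fragments = NA_character_, is_decoy = TRUE,
        true_precursor = NA_character_, true_seq = NA_character_,
        true_carbamidomethyl = NA_integer_, true_oxidation = NA_integer_,
        true_pyroglu = NA, true_amide = NA, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default 26-pool stage/sex design
#'
#' Three pools for sexually undifferentiated stage 0, four pools for male
#' stages 1 and 2, three for male stage 3, and four for female stages
#' 1-3: 26 pools, stage sizes 3/8/8/7.
#'
#' @return Named integer vector of pool counts per condition.
#' @export
default_design <- function() {
  c(St0U = 3L, St1M = 4L, St2M = 4L, St3M = 3L,
    St1F = 4L, St2F = 4L, St3F = 4L)
}

#' Generate a stage-structured negative-binomial count matrix
#'
#' Per-gene base means are log-normal; counts are negative binomial with
#' the given dispersion (Poisson when `dispersion = 0`) around
#' `mean x stage multiplier`. Differential genes follow the three
#' stage-profile classes: group I declines geometrically from stage 0 to
#' stage 3 (`effect, effect^(2/3), effect^(1/3), 1`), group II peaks at
#' stage 3 (`1, 1, 1, effect`), group III has a trough at stage 2
#' (`effect, effect, 1, effect`). There is no sex effect.
#'
#' The panel of interest (`n_genes`, named `geneNNN`) is embedded in a
#' larger matrix with `n_background` stage-invariant background genes
#' (named `bgNNNN`), emulating the rest of the transcriptome: TPM is a
#' relative measure, so without a realistic denominator the differential
#' panel members would induce compositional (anti-correlated) artifacts
#' in the null genes.
#'
#' @param n_genes,n_de Panel size and number of differential genes
#'   (defaults 96 and 25).
#' @param effect Fold change (> 1; `effect = 1` makes every gene null).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param design Named pool counts, `StXS` = stage X, sex S (default
#'   [default_design()]).
#' @param n_background Stage-invariant background genes included in the
#'   matrix (default 900).
#' @param base_meanlog,base_sdlog Log-normal baseline parameters.
#' @param len_range Transcript length range in nt.
#' @param seed Optional RNG seed.
#' @return List of class `count_truth`: `counts` (genes x samples;
#'   panel rows first), `lengths`, `meta` (`sample`, `stage`, `sex`),
#'   `de_labels` (panel genes only), `npp_ids` (panel row names).
#' @export
gen_counts <- function(n_genes = 96L, n_de = 25L, effect = 2.5,
                       dispersion = 0.05, design = default_design(),
                       n_background = 900L, base_meanlog = log(200),
                       base_sdlog = 1, len_range = c(500L, 3000L),
                       seed = NULL) {
  stopifnot(n_de <= n_genes, effect >= 1, dispersion >= 0,
            n_background >= 0L)
  if (!is.null(seed)) set.seed(seed)
  stage <- as.integer(sub("^St(\\d).*$", "\\1", names(design)))
  sex <- sub("^St\\d", "", names(design))
  meta <- data.frame(
    sample = unlist(mapply(function(nm, k) sprintf("%s_%d", nm, seq_len(k)),
                           names(design), design, SIMPLIFY = FALSE)),
    stage = rep(stage, design), sex = rep(sex, design),
    stringsAsFactors = FALSE)
  per_stage <- table(factor(meta$stage, levels = 0:3))
  if (any(per_stage < 2L)) stop("design needs >= 2 samples in every stage")
  mult <- rbind(none = c(1, 1, 1, 1),
                I    = c(effect, effect^(2 / 3), effect^(1 / 3), 1),
                II   = c(1, 1, 1, effect),
                III  = c(effect, effect, 1, effect))
  de_labels <- rep("none", n_genes)
  if (n_de > 0L) {
    de_labels[seq_len(n_de)] <- rep(c("I", "II", "III"),
                                    length.out = n_de)
  }
  ntot <- n_genes + n_background
  gene_labels <- c(de_labels, rep("none", n_background))
  base <- stats::rlnorm(ntot, base_meanlog, base_sdlog)
  lengths <- sample(len_range[[1L]]:len_range[[2L]], ntot, replace = TRUE)
  ids <- c(sprintf("gene%03d", seq_len(n_genes)),
           if (n_background > 0L) sprintf("bg%04d", seq_len(n_background)))
  counts <- matrix(0L, ntot, nrow(meta),
                   dimnames = list(ids, meta$sample))
  for (g in seq_len(ntot)) {
    mu <- base[[g]] * mult[gene_labels[[g]], meta$stage + 1L]
    counts[g, ] <- if (dispersion == 0) stats::rpois(nrow(meta), mu)
                   else stats::rnbinom(nrow(meta), mu = mu,
                                       size = 1 / dispersion)
  }
  de_labels <- stats::setNames(de_labels, ids[seq_len(n_genes)])
  names(lengths) <- ids
  structure(list(counts = counts, lengths = lengths, meta = meta,
                 de_labels = de_labels, npp_ids = ids[seq_len(n_genes)]),
            class = "count_truth")
}
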