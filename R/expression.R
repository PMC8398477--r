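#' TPM normalization (transcripts per kilobase per million reads)
#'
#' Per sample: `rate_g = count_g / (length_g / 1000)`, then
#' `TPM_g = rate_g / sum(rates) * 1e6`, so every column sums to one
#' million. Entries are categorized as `null_low` (TPM < 1), `high`
#' (TPM > 60) or `mid`.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param lengths Per-gene effective transcript length in nt (> 0).
#' @param low,high Category cut points (defaults 1 and 60).
#' @return List of class `tpm_matrix`: `values` (numeric matrix) and
#'   `category` (character matrix).
#' @export
tpm <- function(counts, lengths, low = 1, high = 60) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  zero <- colSums(counts) == 0
  if (any(zero)) {
    nm <- colnames(counts)[zero] %||% which(zero)
    stop("all-zero count column for sample: ", paste(nm, collapse = ", "))
  }
  rate <- counts / (lengths / 1000)
  values <- sweep(rate, 2, colSums(rate), "/") * 1e6
  category <- matrix("mid", nrow(values), ncol(values),
                     dimnames = dimnames(values))
  category[values < low] <- "null_low"
  category[values > high] <- "high"
  structure(list(values = values, category = category),
            class = "tpm_matrix")
}

#' Principal component analysis of samples
#'
#' SVD-based PCA of the centered samples x genes matrix (via
#' [stats::prcomp()]). The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so results are deterministic.
#'
#' @param mat Numeric matrix, genes x samples (e.g. `tpm(...)$values`).
#' @param center,scale Passed to [stats::prcomp()] (defaults TRUE, FALSE).
#' @return List: `scores` (samples x components), `loadings` (genes x
#'   components), `variance_explained` (fractions summing to 1).
#' @export
pca_samples <- function(mat, center = TRUE, scale = FALSE) {
  x <- t(as.matrix(mat))
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  tot <- sum(apply(x, 2, stats::var))
  if (tot == 0) {
    warning("constant matrix: zero variance explained on all axes")
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k),
                loadings = matrix(0, ncol(x), k),
                variance_explained = rep(0, k)))
  }
  p <- stats::prcomp(x, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[[which.max(abs(v))]])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       variance_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) via [stats::hclust()].
#'
#' @param mat Numeric matrix; rows are the items clustered.
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method (default `"average"`).
#' @return List: `tree` (an `hclust` object), `order` (leaf order),
#'   `heights` (merge heights).
#' @export
cluster_profiles <- function(mat, distance = "euclidean",
                             linkage = "average") {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("NA/NaN in matrix")
  if (nrow(mat) < 2L) stop("need at least 2 items to cluster")
  h <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  list(tree = h, order = h$order, heights = h$height)
}

#' One-way ANOVA with Tukey HSD post hoc test
#'
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with p from the F
#' distribution; all pairwise stage contrasts are tested with Tukey's
#' honestly-significant-difference procedure (studentized range
#' distribution) and summarized as a compact letter display, assigned
#' from the highest group mean downward. When all groups have zero
#' within-group variance and equal means, F is defined as 0 with p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `de_result`: `F`, `p`, `df`, `group_means`,
#'   `tukey` (pairwise table), `letters` (named character vector).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  stopifnot(length(groups) == N, k >= 2L, all(table(groups) >= 2L))
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    Fstat <- 0; p <- 1
  } else if (ssw == 0) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  msw <- if (df2 > 0) ssw / df2 else 0
  pairs <- utils::combn(levels(groups), 2)
  tk <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p_adj = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(msw / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tk$p_adj[[i]] <- if (se == 0) {
      if (means[[g1]] == means[[g2]]) 1 else 0
    } else {
      stats::ptukey(abs(means[[g2]] - means[[g1]]) / se, k, df2,
                    lower.tail = FALSE)
    }
  }
  rownames(tk) <- NULL
  letters_out <- compact_letters(levels(groups), means, tk, alpha)
  structure(list(F = Fstat, p = p, df = c(df1, df2), group_means = means,
                 tukey = tk, letters = letters_out),
            class = "de_result")
}

# Compact letter display via insert-and-absorb: start from one class
# containing all groups; each significant pair splits every class that
# holds both; subset classes are absorbed. Letters are assigned in order
# of decreasing group mean.
#' @keywords internal
compact_letters <- function(groups, means, tukey, alpha) {
  classes <- list(groups)
  sig <- tukey[!is.na(tukey$p_adj) & tukey$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[[i]]; g2 <- sig$group2[[i]]
    nxt <- list()
    for (cl in classes) {
      if (g1 %in% cl && g2 %in% cl) {
        nxt[[length(nxt) + 1L]] <- setdiff(cl, g1)
        nxt[[length(nxt) + 1L]] <- setdiff(cl, g2)
      } else nxt[[length(nxt) + 1L]] <- cl
    }
    # absorb classes contained in another
    keep <- vapply(seq_along(nxt), function(a) {
      !any(vapply(seq_along(nxt), function(b) {
        a != b && all(nxt[[a]] %in% nxt[[b]]) &&
          (length(nxt[[b]]) > length(nxt[[a]]) || b < a)
      }, logical(1)))
    }, logical(1))
    classes <- nxt[keep]
  }
  ord <- order(-vapply(classes, function(cl) max(means[cl]), 0))
  classes <- classes[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(classes)) {
    lab <- letters[[i]]
    out[classes[[i]]] <- paste0(out[classes[[i]]], lab)
  }
  out[order(names(out))]
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[[1L]], x$df[[2L]], x$F, x$p))
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Classify a stage-expression profile into groups I/II/III
#'
#' With tolerance `tau = tolerance_frac * (max - min)` of the four stage
#' means: group I is highest expression at the start of the cycle
#' (argmax at stage 0 or 1) followed by a decline through stage 2 to
#' stage 3 within `tau`; group II is highest expression at stage 3;
#' group III is lowest expression at stage 2 with both neighbours
#' exceeding it by more than `tau`. Precedence I > II > III; anything
#' else is `none`.
#'
#' @param stage_means Numeric vector of length 4 (stages 0-3, sexes
#'   pooled).
#' @param tolerance_frac Tolerance as a fraction of the mean range.
#' @return One of `"I"`, `"II"`, `"III"`, `"none"`.
#' @export
classify_profile <- function(stage_means, tolerance_frac = 0.05) {
  if (length(stage_means) != 4L || anyNA(stage_means))
    stop("need means for all four stages")
  m <- as.numeric(stage_means)
  tau <- tolerance_frac * (max(m) - min(m))
  amax <- which.max(m)
  if (amax %in% c(1L, 2L) &&
      m[[3L]] <= max(m[[1L]], m[[2L]]) + tau &&
      m[[4L]] <= m[[3L]] + tau)
    return("I")
  if (amax == 4L) return("II")
  if (which.min(m) == 3L &&
      max(m[[1L]], m[[2L]]) > m[[3L]] + tau &&
      m[[4L]] > m[[3L]] + tau)
    return("III")
  "none"
}

#' Stage-differential expression scan over NPP transcripts
#'
#' Runs [anova_tukey()] per gene on the stage factor (sexes pooled by
#' default) on `log2(TPM + 1)` (or raw TPM), applies [classify_profile()]
#' to the significant genes, and reports Benjamini-Hochberg adjusted
#' p-values alongside the raw ones.
#'
#' @param tpm_values Numeric TPM matrix, genes x samples.
#' @param meta data.frame with per-sample `stage` (0-3) and `sex`
#'   (U/F/M), rows aligned with the columns of `tpm_values`.
#' @param npp_ids Genes to test (default all rows).
#' @param alpha Raw-p significance level (default 0.05).
#' @param pool_sexes Pool sexes within stage (default `TRUE`; when
#'   `FALSE` the factor is the stage-sex interaction).
#' @param log2 Test on `log2(TPM + 1)` (default `TRUE`).
#' @return data.frame: `gene_id`, `F`, `p`, `p_bh`, stage means (TPM
#'   scale), `letters`, `significant`, `group`.
#' @export
de_scan <- function(tpm_values, meta, npp_ids = rownames(tpm_values),
                    alpha = 0.05, pool_sexes = TRUE, log2 = TRUE) {
  stopifnot(nrow(meta) == ncol(tpm_values), all(meta$stage %in% 0:3))
  if (is.null(npp_ids)) npp_ids <- seq_len(nrow(tpm_values))
  fac <- if (pool_sexes) factor(meta$stage)
         else interaction(meta$stage, meta$sex, drop = TRUE)
  rows <- lapply(npp_ids, function(g) {
    y <- tpm_values[g, ]
    yt <- if (log2) base::log2(y + 1) else y
    at <- anova_tukey(yt, fac, alpha = alpha)
    stage_means <- tapply(y, meta$stage, mean)[as.character(0:3)]
    sig <- at$p < alpha
    data.frame(gene_id = as.character(g), F = at$F, p = at$p,
               mean_st0 = stage_means[[1L]], mean_st1 = stage_means[[2L]],
               mean_st2 = stage_means[[3L]], mean_st3 = stage_means[[4L]],
               letters = paste(at$letters, collapse = "/"),
               significant = sig,
               group = if (sig) classify_profile(stage_means) else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[, c("gene_id", "F", "p", "p_bh", "mean_st0", "mean_st1", "mean_st2",
          "mean_st3", "letters", "significant", "group")]
}
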