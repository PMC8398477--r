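#' Default pipeline configuration
#'
#' Every stage parameter of the pipeline with its default. Paper-derived
#' defaults: E-value threshold 1.3, precursor length cap 150, precursor
#' mass tolerance 30 ppm, fragment tolerance 0.05 Da, FDR 0.001, ANOVA
#' alpha 0.05, TPM category cuts 1 and 60.
#'
#' @param seed Integer seed used for every stochastic stage.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_precursors = 20L, n_peptides = 3L, p_amidated = 0.5,
                    p_pyroglu = 0.2, p_monobasic = 0, utr_len = 30L,
                    ppm_sd = 8, p_modified = 0.3, n_decoys = 20L,
                    with_fragments = TRUE, n_genes = 96L, n_de = 25L,
                    effect = 2.5, dispersion = 0.05,
                    n_background = 900L),
    orfs = list(min_len_aa = 30L, require_start = TRUE),
    screen = list(e_max = 1.3, len_max = 150L, require_signal = TRUE,
                  require_sites = TRUE, length_mode = "soft"),
    process = list(include_monobasic = TRUE, cut_monobasic = FALSE,
                   pyroglu = TRUE, allow_terminal_amide = FALSE),
    msmatch = list(ppm_tol = 30, frag_tol = 0.05, fdr_max = 0.001,
                   mode = "mature", max_mods = 3L),
    express = list(alpha = 0.05, pool_sexes = TRUE, log2 = TRUE,
                   tpm_low = 1, tpm_high = 60)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; numeric ranges are checked before any
#' stage runs.
#'
#' @param config Nested list (as from [pipeline_config()] or
#'   [read_config()]).
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  ref <- pipeline_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stop("unknown config section: ", unknown[[1L]])
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad))
      stop("unknown config key: ", sec, "$", bad[[1L]])
  }
  cfg <- utils::modifyList(ref, config)
  with(cfg$screen, stopifnot(e_max > 0, len_max > 0))
  with(cfg$msmatch, stopifnot(ppm_tol > 0, frag_tol > 0, fdr_max > 0,
                              fdr_max <= 1))
  with(cfg$express, stopifnot(alpha >= 0, alpha <= 1, tpm_low < tpm_high))
  with(cfg$simulate, stopifnot(n_de <= n_genes, effect >= 1,
                               dispersion >= 0, ppm_sd >= 0))
  invisible(cfg)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file with the [pipeline_config()] structure (missing
#'   keys take their defaults).
#' @return Validated `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- validate_config(cfg)
  class(out) <- "pipeline_config"
  out
}

#' Run the pipeline end to end on simulated data
#'
#' Executes simulate, orfs, screen, process, msmatch and express in
#' order (a subset is selectable), writing FASTA/TSV artifacts and a
#' machine-readable JSON manifest (inputs, seeds, constant-table version)
#' to `outdir`. Deterministic given `config$seed`.
#'
#' @param config A `pipeline_config` (validated before any stage runs).
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "nppipe_run",
                         stages = c("simulate", "orfs", "screen", "process",
                                    "msmatch", "express")) {
  cfg <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- cfg$simulate

  truths <- lapply(seq_len(sim$n_precursors), function(i) {
    gen_precursor(n_peptides = sim$n_peptides, p_amidated = sim$p_amidated,
                  p_pyroglu = sim$p_pyroglu, p_monobasic = sim$p_monobasic,
                  id = sprintf("prec%03d", i), seed = cfg$seed + i)
  })

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      prots <- vapply(truths, `[[`, "", "sequence")
      names(prots) <- vapply(truths, `[[`, "", "id")
      art$precursors_fasta <<- file.path(outdir, "precursors.fasta")
      write_fasta(prots, art$precursors_fasta)
      tx <- gen_transcripts(truths, utr_len = sim$utr_len,
                            seed = cfg$seed + 1000L)
      art$transcripts_fasta <<- file.path(outdir, "transcripts.fasta")
      write_fasta(tx$records, art$transcripts_fasta)
      obs <- gen_ms_observations(truths, ppm_sd = sim$ppm_sd,
                                 p_modified = sim$p_modified,
                                 n_decoys = sim$n_decoys,
                                 with_fragments = sim$with_fragments,
                                 seed = cfg$seed + 2000L)
      art$observations_tsv <<- file.path(outdir, "observations.tsv")
      utils::write.table(obs, art$observations_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ct <- gen_counts(n_genes = sim$n_genes, n_de = sim$n_de,
                       effect = sim$effect, dispersion = sim$dispersion,
                       n_background = sim$n_background,
                       seed = cfg$seed + 3000L)
      art$counts_tsv <<- file.path(outdir, "counts.tsv")
      utils::write.table(
        data.frame(gene = rownames(ct$counts), length = ct$lengths,
                   ct$counts, check.names = FALSE),
        art$counts_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      art$meta_tsv <<- file.path(outdir, "meta.tsv")
      utils::write.table(ct$meta, art$meta_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      truth <- list(
        peptides = lapply(truths, function(t)
          c(list(id = t$id, signal_end = t$signal_end),
            list(peptides = t$peptides))),
        de_labels = as.list(ct$de_labels))
      art$truth_json <<- file.path(outdir, "truth.json")
      jsonlite::write_json(truth, art$truth_json, auto_unbox = TRUE,
                           digits = NA)
    })
  }

  orf_df <- NULL
  if ("orfs" %in% stages) {
    run_stage("orfs", function() {
      tx <- gen_transcripts(truths, utr_len = sim$utr_len,
                            seed = cfg$seed + 1000L)
      orf_df <<- do.call(rbind, lapply(names(tx$records), function(id) {
        find_orfs(tx$records[[id]], id = id,
                  min_len_aa = cfg$orfs$min_len_aa,
                  require_start = cfg$orfs$require_start)
      }))
      art$orfs_fasta <<- file.path(outdir, "orfs.fasta")
      prot <- orf_df$protein
      names(prot) <- sprintf("%s|%+d|%d-%d", orf_df$contig_id, orf_df$frame,
                             orf_df$nt_start, orf_df$nt_end)
      write_fasta(prot, art$orfs_fasta)
    })
  }

  screen_df <- NULL
  targets <- vapply(truths, `[[`, "", "sequence")
  names(targets) <- vapply(truths, `[[`, "", "id")
  if ("screen" %in% stages) {
    run_stage("screen", function() {
      cand <- if (!is.null(orf_df)) {
        p <- orf_df$protein
        names(p) <- sprintf("%s|%+d", orf_df$contig_id, orf_df$frame)
        p[!duplicated(names(p))]
      } else targets
      screen_df <<- screen_candidates(
        targets, cand, e_max = cfg$screen$e_max,
        len_max = cfg$screen$len_max,
        require_signal = cfg$screen$require_signal,
        require_sites = cfg$screen$require_sites,
        length_mode = cfg$screen$length_mode)
      art$screen_tsv <<- file.path(outdir, "screen.tsv")
      utils::write.table(screen_df, art$screen_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  anns <- NULL
  if ("process" %in% stages) {
    run_stage("process", function() {
      anns <<- lapply(truths, function(t) {
        annotate_precursor(t$sequence, id = t$id,
                           include_monobasic = cfg$process$include_monobasic,
                           cut_monobasic = cfg$process$cut_monobasic,
                           pyroglu = cfg$process$pyroglu,
                           allow_terminal_amide =
                             cfg$process$allow_terminal_amide)
      })
      art$annotation_tsv <<- file.path(outdir, "annotations.tsv")
      write_annotation_table(anns, art$annotation_tsv)
      peps <- do.call(rbind, lapply(anns, function(a) {
        if (!nrow(a$peptides)) return(NULL)
        data.frame(id = sprintf("%s|%s%s%s", a$protein_id,
                                ifelse(a$peptides$pyroglu, "pyroGlu-", ""),
                                a$peptides$seq,
                                ifelse(a$peptides$amidated, "-amide", "")),
                   seq = a$peptides$seq, stringsAsFactors = FALSE)
      }))
      pv <- peps$seq
      names(pv) <- make.unique(peps$id)
      art$peptides_fasta <<- file.path(outdir, "peptides.fasta")
      write_fasta(pv, art$peptides_fasta)
    })
  }

  if ("msmatch" %in% stages) {
    run_stage("msmatch", function() {
      if (is.null(anns)) anns <- lapply(truths, truth_annotation)
      obs <- gen_ms_observations(truths, ppm_sd = sim$ppm_sd,
                                 p_modified = sim$p_modified,
                                 n_decoys = sim$n_decoys,
                                 with_fragments = sim$with_fragments,
                                 seed = cfg$seed + 2000L)
      cand <- build_candidates(anns, mode = cfg$msmatch$mode,
                               max_mods = cfg$msmatch$max_mods)
      dec <- reverse_decoys(cand)
      tm <- match_peptides(obs, cand, ppm_tol = cfg$msmatch$ppm_tol,
                           frag_tol = cfg$msmatch$frag_tol)
      dm <- match_peptides(obs, dec, ppm_tol = cfg$msmatch$ppm_tol,
                           frag_tol = cfg$msmatch$frag_tol)
      filt <- fdr_filter(tm[tm$best, , drop = FALSE],
                         dm[dm$best, , drop = FALSE],
                         fdr_max = cfg$msmatch$fdr_max)
      art$matches_tsv <<- file.path(outdir, "matches.tsv")
      utils::write.table(filt$matches, art$matches_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  if ("express" %in% stages) {
    run_stage("express", function() {
      ct <- gen_counts(n_genes = sim$n_genes, n_de = sim$n_de,
                       effect = sim$effect, dispersion = sim$dispersion,
                       n_background = sim$n_background,
                       seed = cfg$seed + 3000L)
      tp <- tpm(ct$counts, ct$lengths, low = cfg$express$tpm_low,
                high = cfg$express$tpm_high)
      art$tpm_tsv <<- file.path(outdir, "tpm.tsv")
      utils::write.table(
        data.frame(gene = rownames(tp$values), tp$values,
                   check.names = FALSE),
        art$tpm_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      pc <- pca_samples(tp$values)
      art$pca_tsv <<- file.path(outdir, "pca_scores.tsv")
      utils::write.table(
        data.frame(sample = colnames(tp$values), pc$scores,
                   check.names = FALSE),
        art$pca_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      cl <- cluster_profiles(t(base::log2(tp$values + 1)))
      art$cluster_order <<- file.path(outdir, "cluster_order.txt")
      writeLines(colnames(tp$values)[cl$order], art$cluster_order)
      de <- de_scan(tp$values, ct$meta, npp_ids = ct$npp_ids,
                    alpha = cfg$express$alpha,
                    pool_sexes = cfg$express$pool_sexes,
                    log2 = cfg$express$log2)
      art$de_tsv <<- file.path(outdir, "de_results.tsv")
      utils::write.table(de, art$de_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }

  manifest <- list(seed = cfg$seed, stages = stages, config = cfg,
                   constants_version = CONSTANTS_VERSION,
                   artifacts = art)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(art)
}
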