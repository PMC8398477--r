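test_that("cleavage sites follow the maximal-run rule", {
  s <- find_cleavage_sites("AAAKRAAA")
  expect_equal(s$position, 5L)
  expect_equal(s$kind, "dibasic")
  expect_equal(s$motif, "KR")

  expect_equal(nrow(find_cleavage_sites("AAARAAA")), 0L)
  s <- find_cleavage_sites("AAARAAA", include_monobasic = TRUE)
  expect_equal(s$position, 4L)
  expect_equal(s$kind, "monobasic")

  s <- find_cleavage_sites("AAKRRKAA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$kind, "multibasic")
  expect_equal(s$motif, "KRRK")
  expect_equal(s$position, 6L)
})

test_that("maximal runs agree with a brute-force scan", {
  set.seed(71)
  for (i in 1:50) {
    s <- paste(sample(c("A", "G", "K", "R", "S"), 40, replace = TRUE),
               collapse = "")
    found <- find_cleavage_sites(s, include_monobasic = TRUE)
    aa <- strsplit(s, "")[[1]]
    basic <- aa %in% c("K", "R")
    # brute force: positions ending a maximal run
    ends <- which(basic & c(basic[-1] == FALSE, TRUE))
    starts <- which(basic & c(TRUE, basic[-length(basic)] == FALSE))
    expect_equal(found$position, ends)
    expect_equal(nchar(found$motif), ends - starts + 1L)
  }
})

test_that("the GNamide-family propeptide processes to its known products", {
  prop <- "QTFGWGGAGNGKRSSFA"
  sites <- find_cleavage_sites(prop)
  p <- derive_peptides(prop, 0L, sites)
  expect_equal(p$seq, c("QTFGWGGAGN", "SSFA"))
  expect_true(p$amidated[[1]])   # sacrificial Gly before KR
  expect_true(p$pyroglu[[1]])    # N-terminal Gln
  expect_false(p$amidated[[2]])
  expect_false(p$pyroglu[[2]])
})

test_that("degenerate propeptides are handled", {
  # no sites: the whole propeptide is one unamidated peptide
  p <- derive_peptides("ASTFNQH", 0L,
                       find_cleavage_sites("ASTFNQH"))
  expect_equal(p$seq, "ASTFNQH")
  expect_false(p$amidated)
  # adjacent sites produce empty segments that are dropped silently
  prop <- "AAKRKRAA" # one multibasic run, two flanking segments
  p <- derive_peptides(prop, 0L, find_cleavage_sites(prop))
  expect_equal(p$seq, c("AA", "AA"))
  # duplicate sites error
  s <- find_cleavage_sites("AAKRAA")
  expect_error(derive_peptides("AAKRAA", 0L, rbind(s, s)), "duplicate")
})

test_that("annotation round-trips generator truths exactly", {
  for (i in 1:200) {
    tr <- gen_precursor(n_peptides = sample(1:4, 1), p_amidated = 0.6,
                        p_pyroglu = 0.3, p_monobasic = 0,
                        id = sprintf("rt%03d", i), seed = 9000 + i)
    ann <- annotate_precursor(tr$sequence, id = tr$id)
    expect_equal(ann$signal$cleavage_after, tr$signal_end)
    expect_equal(ann$peptides$seq, tr$peptides$seq)
    expect_equal(ann$peptides$start, tr$peptides$start)
    expect_equal(ann$peptides$end, tr$peptides$end)
    expect_equal(ann$peptides$amidated, tr$peptides$amidated)
    expect_equal(ann$peptides$pyroglu, tr$peptides$pyroglu)
    expect_true(check_reconstruction(ann))
  }
})

test_that("reconstruction holds with monobasic sites and strict mode errors", {
  # monobasic sites are annotate-only by default: reconstruction must
  # still hold because the basic residue stays inside a peptide body
  for (i in 1:50) {
    tr <- gen_precursor(p_monobasic = 0.5, id = "mb", seed = 9500 + i)
    ann <- annotate_precursor(tr$sequence, id = "mb")
    expect_true(check_reconstruction(ann))
  }
  expect_error(annotate_precursor("ASTFNQHWERTYK", id = "short"),
               "signal")
  expect_warning(
    ann <- annotate_precursor(strrep("ANQSTKRED", 5), id = "lenient",
                              strict = FALSE),
    "propeptide")
  expect_true(check_reconstruction(ann))
})

test_that("amidation only ever consumes one glycine per peptide", {
  set.seed(75)
  for (i in 1:50) {
    tr <- gen_precursor(p_amidated = 1, n_peptides = 3, seed = 9800 + i)
    ann <- annotate_precursor(tr$sequence, id = "am")
    n_amid <- sum(ann$peptides$amidated)
    total_len <- nchar(ann$sequence)
    parts_len <- ann$signal$cleavage_after + sum(nchar(ann$peptides$seq)) +
      sum(nchar(ann$sites$motif[ann$sites$cut]))
    expect_equal(total_len - parts_len, n_amid)
    # every amidated truth peptide ends ...G|basic in the full sequence
    for (j in which(tr$peptides$amidated))
      expect_equal(substr(tr$sequence, tr$peptides$end[[j]] + 1L,
                          tr$peptides$end[[j]] + 1L), "G")
  }
})

test_that("partially processed forms enumerate site-skipping merges", {
  tr <- gen_precursor(n_peptides = 3, p_amidated = 1, seed = 81)
  ann <- annotate_precursor(tr$sequence, id = "pp")
  expect_equal(nrow(ann$peptides), 3L)
  forms <- partially_processed_forms(ann, max_missed_sites = 1)
  expect_equal(nrow(forms), 5L) # 3 singletons + 2 two-mers
  forms0 <- partially_processed_forms(ann, max_missed_sites = 0)
  expect_equal(forms0$seq, ann$peptides$seq)
  # merged sequence equals the precursor substring over the merged span
  for (k in seq_len(nrow(forms)))
    expect_equal(forms$seq[[k]],
                 substr(ann$sequence, forms$start[[k]], forms$end[[k]]))
  # a two-mer retains the internal site motif in its sequence
  two <- forms[forms$end == ann$peptides$end[[2]] &
                 forms$start == ann$peptides$start[[1]], ]
  expect_match(two$seq, "[KR][KR]")
})
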