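test_that("monoisotopic masses match hand sums and composition oracle", {
  expect_equal(monoisotopic_mass("PYLLS"), 591.3268, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("G"), 57.02146 + 18.010565)

  set.seed(91)
  for (i in 1:100) {
    sq <- random_protein(sample(4:25, 1))
    aa <- strsplit(sq, "")[[1]]
    carb <- if (any(aa == "C")) sample(0:sum(aa == "C"), 1) else 0
    ox <- if (any(aa == "M")) sample(0:sum(aa == "M"), 1) else 0
    pg <- aa[[1]] == "Q" && runif(1) < 0.5
    am <- runif(1) < 0.5
    expect_equal(monoisotopic_mass(sq, carb, ox, pg, am),
                 oracle_mass(sq, carb, ox, pg, am), tolerance = 1e-4)
  }
  expect_error(monoisotopic_mass("AZB"), "unknown residue")
  expect_error(monoisotopic_mass("ACD", carbamidomethyl = 2), "Cys")
  expect_error(monoisotopic_mass("ACD", pyroglu = TRUE), "Gln")
})

test_that("modification deltas are additive", {
  set.seed(92)
  for (i in 1:100) {
    sq <- random_protein(sample(4:30, 1))
    expect_equal(monoisotopic_mass(sq, amide = TRUE),
                 monoisotopic_mass(sq) - 0.98402)
  }
  # mass additivity over random splits: mass(AB) = mass(A) + mass(B) - water
  for (i in 1:50) {
    sq <- random_protein(sample(6:30, 1))
    k <- sample(2:(nchar(sq) - 2), 1)
    expect_equal(monoisotopic_mass(sq),
                 monoisotopic_mass(substr(sq, 1, k)) +
                   monoisotopic_mass(substr(sq, k + 1, nchar(sq))) -
                   18.010565,
                 tolerance = 1e-9)
  }
})

test_that("ppm error is signed and antisymmetric to first order", {
  expect_equal(ppm_error(1000, 1000), 0)
  expect_equal(ppm_error(1000.03, 1000), 30)
  for (pair in list(c(500.1, 500), c(1200.2, 1200.1), c(3000, 2999.9))) {
    expect_equal(ppm_error(pair[1], pair[2]),
                 -ppm_error(pair[2], pair[1]),
                 tolerance = 1e-3 * abs(ppm_error(pair[1], pair[2])))
  }
})

test_that("b/y ladders obey the complementarity identity exactly", {
  set.seed(93)
  for (i in 1:30) {
    sq <- random_protein(sample(4:20, 1))
    am <- runif(1) < 0.5
    lad <- fragment_ladder(sq, amide = am)
    L <- nchar(sq)
    M <- monoisotopic_mass(sq, amide = am)
    for (k in seq_len(L - 1)) {
      expect_equal(lad$b[[k]] + lad$y[[L - k]], M + 2 * 1.00739,
                   tolerance = 1e-9)
    }
  }
})

test_that("no_enzyme candidate counts follow the substring formula", {
  tr <- gen_precursor(seed = 95)
  prec20 <- substr(tr$sequence, 1, 20)
  ann <- structure(list(protein_id = "x", sequence = prec20,
                        signal = nppipe:::new_signal_prediction(TRUE, 14L, 1),
                        sites = data.frame(position = integer(),
                                           kind = character(),
                                           motif = character(), cut = logical()),
                        peptides = nppipe:::empty_peptide_df()),
                   class = "precursor_annotation")
  cand <- build_candidates(ann, mode = "no_enzyme", len_range = c(4, 60),
                           max_mods = 0)
  # sum_{l=4..20} (21 - l) = 153 unmodified substrings
  expect_equal(nrow(cand), 153L)
  expect_true(all(vapply(cand$seq, grepl, logical(1), x = prec20,
                         fixed = TRUE)))
  expect_error(build_candidates(ann, mode = "no_enzyme",
                                len_range = c(10, 4)), "len_range")
})

test_that("mature-mode candidates are precursor substrings with mod combos", {
  tr <- gen_precursor(n_peptides = 2, p_amidated = 1, seed = 96)
  ann <- truth_annotation(tr)
  cand <- build_candidates(ann, mode = "mature")
  expect_true(all(vapply(cand$seq, grepl, logical(1), x = tr$sequence,
                         fixed = TRUE)))
  # oxidation combinations enumerate 0..nM for a 2-Met peptide
  ann2 <- ann
  ann2$sequence <- paste0(strrep("L", 14), "AMSTMF")
  ann2$signal <- nppipe:::new_signal_prediction(TRUE, 14L, 1)
  ann2$peptides <- data.frame(seq = "AMSTMF", start = 15L, end = 20L,
                              amidated = FALSE, pyroglu = FALSE, n_cys = 0,
                              evidence = "predicted",
                              stringsAsFactors = FALSE)
  ann2$sites <- ann$sites[0, ]
  cand2 <- build_candidates(ann2, mode = "mature", max_trunc = 0)
  expect_setequal(cand2$oxidation[cand2$seq == "AMSTMF"], 0:2)
})

test_that("matching respects the precursor tolerance strictly", {
  cand <- data.frame(candidate_id = "c1", precursor_id = "p", seq = "PYLLS",
                     start = 1L, end = 5L, carbamidomethyl = 0L,
                     oxidation = 0L, pyroglu = FALSE, amide = FALSE,
                     mass = monoisotopic_mass("PYLLS"), is_decoy = FALSE,
                     stringsAsFactors = FALSE)
  m0 <- monoisotopic_mass("PYLLS")
  obs <- data.frame(source_id = c("in", "out"),
                    obs_mass = m0 * c(1 + 29e-6, 1 + 31e-6),
                    stringsAsFactors = FALSE)
  m <- match_peptides(obs, cand, ppm_tol = 30)
  expect_equal(m$source_id, "in")
  expect_equal(m$ppm_error, 29, tolerance = 1e-6)
})

test_that("zero-noise observations match their truth exactly", {
  truths <- lapply(1:5, function(i)
    gen_precursor(id = sprintf("z%d", i), seed = 970 + i))
  obs <- gen_ms_observations(truths, ppm_sd = 0, n_decoys = 0, seed = 4)
  cand <- build_candidates(lapply(truths, truth_annotation), mode = "mature")
  m <- match_peptides(obs, cand)
  best <- m[m$best, ]
  for (i in seq_len(nrow(obs))) {
    b <- best[best$source_id == obs$source_id[[i]], ]
    expect_equal(nrow(b), 1L)
    expect_equal(abs(ppm_error(obs$obs_mass[[i]], b$mass)), 0,
                 tolerance = 1e-6)
  }
  # decoy-only observations match nothing
  obs_d <- gen_ms_observations(truths, ppm_sd = 0, n_decoys = 15, seed = 5)
  obs_d <- obs_d[obs_d$is_decoy, ]
  expect_equal(nrow(match_peptides(obs_d, cand)), 0L)
})

test_that("match results are invariant to candidate order", {
  truths <- lapply(1:3, function(i)
    gen_precursor(id = sprintf("o%d", i), seed = 980 + i))
  obs <- gen_ms_observations(truths, ppm_sd = 5, with_fragments = TRUE,
                             seed = 6)
  cand <- build_candidates(lapply(truths, truth_annotation), mode = "mature")
  m1 <- match_peptides(obs, cand)
  set.seed(1); cand2 <- cand[sample(nrow(cand)), ]
  m2 <- match_peptides(obs, cand2)
  key <- function(m) {
    k <- m[order(m$source_id, m$candidate_id),
           c("source_id", "candidate_id", "score")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(m1), key(m2))
  expect_equal(sort(m1$candidate_id[m1$best]), sort(m2$candidate_id[m2$best]))
})

test_that("FDR filtering handles the degenerate constructions", {
  tm <- data.frame(score = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  dm <- tm[0, , drop = FALSE]
  r <- fdr_filter(tm, dm, fdr_max = 0.001)
  expect_equal(nrow(r$matches), 3L) # zero decoys: everything survives
  # interleaved equal scores: estimated FDR >= 0.5 everywhere
  tm <- data.frame(score = c(1, 1, 2, 2))
  dm <- data.frame(score = c(1, 1, 2, 2))
  r <- fdr_filter(tm, dm, fdr_max = 0.001)
  expect_equal(nrow(r$matches), 0L)
  expect_equal(fdr_filter(tm[0, , drop = FALSE], dm)$matches |> nrow(), 0L)
  # threshold is monotone in fdr_max
  tm <- data.frame(score = seq(1, 0.1, by = -0.1))
  dm <- data.frame(score = c(0.45, 0.15))
  thr <- vapply(c(0.05, 0.2, 0.5), function(f) fdr_filter(tm, dm, f)$threshold, 0)
  expect_true(all(diff(thr) <= 0))
})
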