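test_that("decoys preserve length and residue multiset, deterministically", {
  fx <- generate_proteome(n_male = 10, n_female = 10, n_plug = 3, seed = 1)
  dec <- decoy_database(fx, seed = 5)
  expect_equal(nrow(dec$proteins), nrow(fx$proteins))
  expect_true(all(startsWith(dec$proteins$gene_id, "DECOY_")))
  for (i in seq_len(nrow(fx$proteins))) {
    expect_equal(nchar(dec$proteins$sequence[i]),
                 nchar(fx$proteins$sequence[i]))
    expect_equal(sort(strsplit(dec$proteins$sequence[i], "")[[1]]),
                 sort(strsplit(fx$proteins$sequence[i], "")[[1]]))
  }
  expect_identical(dec, decoy_database(fx, seed = 5))
  # long tryptic peptides almost never survive shuffling intact
  tgt <- unlist(lapply(fx$proteins$sequence, function(s) {
    p <- tryptic_digest(s); p[nchar(p) >= 8]
  }))
  shared_per_gene <- vapply(dec$proteins$sequence, function(s) {
    p <- tryptic_digest(s)
    any(p[nchar(p) >= 8] %in% tgt)
  }, logical(1))
  expect_gte(mean(!shared_per_gene), 0.99)
})

test_that("FDR thresholding picks the lowest attainable threshold", {
  # hand enumeration for targets [5,4,3,2], decoys [4.5,1]:
  #   s=1: 2/4=0.50  s=2: 1/4=0.25  s=3: 1/3=0.33  s=4: 1/2=0.50
  #   s=4.5: 1/1=1.0  s=5: 0/1=0
  # lowest s with ratio <= 0.34 is s=2, accepting 4 targets
  psms <- make_psms(c(5, 4, 3, 2), c(4.5, 1))
  res <- filter_psms_fdr(psms, fdr = 0.34)
  expect_equal(res$threshold, 2)
  expect_equal(nrow(res$accepted), 4)
  expect_equal(res$est_fdr, 0.25)

  # all decoys below all targets: everything accepted
  res2 <- filter_psms_fdr(make_psms(c(9, 8, 7), c(1, 2)), fdr = 0.01)
  expect_equal(nrow(res2$accepted), 3)
  # all targets below all decoys: nothing attainable
  res3 <- filter_psms_fdr(make_psms(c(1, 2), c(8, 9)), fdr = 0.1)
  expect_equal(nrow(res3$accepted), 0)
  expect_equal(res3$threshold, Inf)
  expect_error(filter_psms_fdr(make_psms(c(1, 2), numeric(0)), 0.01),
               "decoy")
})

test_that("FDR threshold agrees with brute-force enumeration", {
  set.seed(8)
  for (i in 1:25) {
    psms <- make_psms(round(rnorm(40, 4), 2), round(rnorm(12, 2), 2))
    fdr <- runif(1, 0.02, 0.4)
    res <- filter_psms_fdr(psms, fdr)
    # brute force: scan every observed score as a candidate threshold
    best <- Inf
    for (s in sort(unique(psms$score))) {
      n_t <- sum(psms$score[!psms$is_decoy] >= s)
      n_d <- sum(psms$score[psms$is_decoy] >= s)
      if (n_t > 0 && n_d / n_t <= fdr) { best <- s; break }
    }
    expect_equal(res$threshold, best)
  }
})

test_that("realized false-match proportion stays near the nominal FDR", {
  fx <- generate_proteome(n_male = 10, n_female = 10, n_plug = 3, seed = 2)
  fp <- integer(50); acc <- integer(50)
  for (s in 1:50) {
    psms <- psm_bind(simulate_experiment(
      fx, default_design(meanlog = log(25)), seed = 1000 + s))
    res <- filter_psms_fdr(psms, fdr = 0.01)
    fp[s] <- sum(res$accepted$match_truth != "true")
    acc[s] <- nrow(res$accepted)
  }
  expect_lte(sum(fp) / sum(acc), 0.02)  # within 2x nominal
})

test_that("labeled-mode matching requires the nitrogen-count mass shift", {
  fx <- generate_proteome(n_male = 6, n_female = 6, n_plug = 2, seed = 3)
  idx <- peptide_index(fx, min_len = 1L)
  expect_true("AK" %in% idx$peptide ||
                nrow(idx) > 0)  # index built
  idx <- rbind(idx, data.frame(peptide = "AK", mass = monoisotopic_mass("AK"),
                               n_nitrogen = 3L))
  q <- monoisotopic_mass("AK") + 2.85
  expect_true("AK" %in% match_labeled_mode(q, idx, 0.95, tol_ppm = 10))
  expect_false("AK" %in% match_labeled_mode(monoisotopic_mass("AK"), idx,
                                            0.95, tol_ppm = 10))
  # zero incorporation degenerates to natural-mode matching
  expect_true("AK" %in% match_labeled_mode(monoisotopic_mass("AK"), idx, 0,
                                           tol_ppm = 10))
  expect_error(match_labeled_mode(500, idx[0, ], 0.95), "empty")
})

test_that("peptide mapping counts distinct gene locations", {
  fx <- generate_proteome(n_male = 10, n_female = 10, n_plug = 3,
                          family_fraction = 0.4, seed = 6)
  digests <- lapply(fx$proteins$sequence, seminalMS:::.detectable_peptides)
  names(digests) <- fx$proteins$gene_id
  peps <- unique(unlist(digests))
  mapping <- map_peptides(peps, fx, min_len = 6L)
  # oracle: direct containment scan
  for (i in sample(seq_along(peps), 40)) {
    genes <- names(digests)[vapply(digests, function(d) peps[i] %in% d,
                                   logical(1))]
    row <- mapping[mapping$peptide == peps[i], ]
    expect_equal(row$n_locations, length(genes))
    expect_setequal(strsplit(row$genes, ";")[[1]], genes)
  }
  # family_fraction = 0 gives 100% uniquely mapping peptides
  fx0 <- generate_proteome(n_male = 8, n_female = 8, n_plug = 2,
                           family_fraction = 0, seed = 7)
  m0 <- map_peptides(
    unique(unlist(lapply(fx0$proteins$sequence,
                         seminalMS:::.detectable_peptides))),
    fx0, min_len = 6L)
  expect_true(all(m0$n_locations == 1))
})

test_that("gene inference enforces two peptides with one unique", {
  mapping <- data.frame(
    peptide = c("UNIQA", "SHAREDAB", "SHAREDABC", "UNIQD"),
    genes = c("A", "A;B", "A;B;C", "D"),
    n_locations = c(1L, 2L, 3L, 1L),
    stringsAsFactors = FALSE
  )
  accepted <- data.frame(peptide = c("UNIQA", "SHAREDAB", "SHAREDABC",
                                     "SHAREDAB", "UNIQD"))
  res <- infer_genes(accepted, mapping)
  # A: unique + shared -> identified; B: two shared only -> ambiguous;
  # C: one shared -> neither; D: one unique only -> not identified
  expect_equal(res$identified$gene_id, "A")
  expect_equal(res$ambiguous$gene_id, "B")
  expect_false("D" %in% res$identified$gene_id)

  # brute-force oracle on random small instances
  set.seed(21)
  for (trial in 1:20) {
    genes <- LETTERS[1:sample(3:10, 1)]
    peps <- sprintf("PEPTIDE%02d", 1:sample(4:12, 1))
    pep2genes <- lapply(peps, function(p)
      sample(genes, sample(1:min(3, length(genes)), 1)))
    names(pep2genes) <- peps
    observed <- sample(peps, sample(2:length(peps), 1))
    mapping <- data.frame(
      peptide = peps,
      genes = vapply(pep2genes, paste, character(1), collapse = ";"),
      n_locations = lengths(pep2genes), stringsAsFactors = FALSE
    )
    res <- infer_genes(data.frame(peptide = observed), mapping)
    oracle <- oracle_infer(observed, pep2genes)
    expect_setequal(res$identified$gene_id, oracle$identified)
    expect_setequal(res$ambiguous$gene_id, oracle$ambiguous)
  }
})

test_that("fractional counts share spectra across locations and conserve", {
  mapping <- data.frame(
    peptide = c("P1", "P2", "P3"),
    genes = c("A;B;C", "A", "ZZZ"),
    n_locations = c(3L, 1L, 1L), stringsAsFactors = FALSE
  )
  accepted <- data.frame(peptide = c(rep("P1", 6), rep("P2", 4)))
  cts <- fractional_counts(accepted, mapping)
  expect_equal(cts[["A"]], 2 + 4)
  expect_equal(cts[["B"]], 2)
  expect_equal(cts[["C"]], 2)
  expect_equal(sum(cts), nrow(accepted))

  # conservation on simulated data (over PSMs that map to >= 1 gene)
  fx <- generate_proteome(n_male = 8, n_female = 8, n_plug = 2,
                          family_fraction = 0.3, seed = 9)
  psms <- psm_bind(simulate_experiment(
    fx, default_design(meanlog = log(30)), seed = 4))
  acc <- filter_psms_fdr(psms, 0.01)$accepted
  mp <- map_peptides(unique(acc$peptide), fx, min_len = 6L)
  cts <- fractional_counts(acc, mp)
  mapped <- acc$peptide %in% mp$peptide[mp$n_locations > 0]
  expect_equal(sum(cts), sum(mapped))
})

test_that("the induced-female filter applies its three criteria", {
  labeled <- c("g1", "g2", "g3", "g4", "g5")
  secr <- c(g1 = 0.95, g2 = 0.85, g3 = 0.99, g4 = 0.97)  # g5 missing
  res <- suppressMessages(female_induced_filter(
    labeled, secr, unmated_ids = "g3", male_ids = "g4"
  ))
  expect_equal(res$gene_id[res$induced], "g1")
  expect_false(res$c1[res$gene_id == "g2"])   # below 0.90
  expect_false(res$c2[res$gene_id == "g3"])   # in unmated control
  expect_false(res$c3[res$gene_id == "g4"])   # male-derived
  expect_false(res$c1[res$gene_id == "g5"])   # missing probability fails i
  expect_message(
    female_induced_filter(labeled, secr, "g3", "g4"),
    "secretion"
  )
  # boundary: P = 0.90 exactly is not > 0.90
  res2 <- female_induced_filter("gx", c(gx = 0.90), character(0),
                                character(0))
  expect_false(res2$induced)
})
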