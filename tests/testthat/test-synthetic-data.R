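test_that("tryptic digest applies the K/R rule with the proline exception", {
  expect_equal(tryptic_digest("AKGR"), c("AK", "GR"))
  expect_equal(tryptic_digest("AKPGR"), "AKPGR")
  expect_equal(tryptic_digest("AKGR", max_missed = 1),
               c("AK", "GR", "AKGR"))
  expect_equal(tryptic_digest("KKK", max_missed = 2),
               c("K", "K", "K", "KK", "KK", "KKK"))
  expect_error(tryptic_digest("AZK"), "'Z'")
  # digest fragments reassemble the protein
  s <- "MKTAYIAKQRQISFVKSHFSR"
  expect_equal(paste(tryptic_digest(s), collapse = ""), s)
})

test_that("proteome generation honors counts, determinism, and disjointness", {
  fx <- generate_proteome(n_male = 20, n_female = 30, n_plug = 7,
                          family_fraction = 0.2, seed = 1)
  expect_s3_class(fx$proteins, "data.frame")
  expect_equal(nrow(fx$proteins), 50)
  expect_equal(sum(fx$proteins$origin == "male_plug"), 7)
  expect_false(anyDuplicated(fx$proteins$gene_id) > 0)
  expect_true(all(nchar(fx$proteins$sequence) > 0))

  # byte-identical FASTA for a repeated seed
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_proteome_fasta(generate_proteome(seed = 1), f1)
  write_proteome_fasta(generate_proteome(seed = 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_proteome_fasta(f1)
  expect_equal(rt$proteins$sequence, generate_proteome(seed = 1)$proteins$sequence)

  # family_fraction = 0: exhaustive digest-and-compare shows no detectable
  # tryptic peptide shared between genes
  fx0 <- generate_proteome(n_male = 15, n_female = 15, n_plug = 3,
                           family_fraction = 0, seed = 2)
  digests <- lapply(fx0$proteins$sequence, seminalMS:::.detectable_peptides)
  all_peps <- unlist(digests)
  expect_false(anyDuplicated(all_peps) > 0)

  # family genes do share a detectable peptide with a family partner
  fams <- split(names(fx$family_map), fx$family_map)
  fams <- fams[lengths(fams) >= 2]
  expect_gt(length(fams), 0)
  for (fam in fams) {
    sets <- lapply(fam, function(g) {
      seminalMS:::.detectable_peptides(
        fx$proteins$sequence[fx$proteins$gene_id == g])
    })
    expect_gt(length(Reduce(intersect, sets)), 0)
  }
  expect_error(generate_proteome(family_fraction = 1), "family_fraction")
  expect_error(generate_proteome(n_plug = 50, n_male = 10), "n_plug")
})

test_that("simulated experiments have the declared replicate structure", {
  fx <- generate_proteome(seed = 1)
  tabs <- simulate_experiment(fx, default_design(), seed = 7)
  expect_length(tabs, 2 * 7 + 2 * 5 + 1)
  expect_named(tabs)
  all_psms <- psm_bind(tabs)
  expect_true(all(c("spectrum_id", "sample_id", "replicate", "peptide",
                    "charge", "observed_mass", "score", "is_decoy",
                    "label_mode_truth") %in% names(all_psms)))
  # determinism
  tabs2 <- simulate_experiment(fx, default_design(), seed = 7)
  expect_identical(tabs, tabs2)
  # the unmated control carries no male-derived spectra
  ctrl <- all_psms[all_psms$sample_id == "unmated1" &
                     all_psms$match_truth == "true", ]
  male_genes <- fx$proteins$gene_id[fx$proteins$origin %in%
                                      c("male_plug", "male_seminal")]
  male_peps <- unique(unlist(lapply(
    fx$proteins$sequence[fx$proteins$gene_id %in% male_genes],
    seminalMS:::.detectable_peptides)))
  expect_false(any(ctrl$peptide %in% male_peps))
})

test_that("zero leakage means every female-origin spectrum is labeled", {
  fx <- generate_proteome(n_male = 8, n_female = 8, n_plug = 2, seed = 3)
  d <- default_design(leakage_rate = 0, meanlog = log(40))
  psms <- psm_bind(simulate_experiment(fx, d, seed = 11))
  fem_peps <- unique(unlist(lapply(
    fx$proteins$sequence[fx$proteins$origin == "female"],
    seminalMS:::.detectable_peptides)))
  fem <- psms[psms$match_truth == "true" & psms$peptide %in% fem_peps, ]
  expect_true(all(fem$label_mode_truth == "labeled"))
  # and labeled masses carry the enrichment shift: reassignment by mass works
  one <- fem[1L, ]
  shift <- n15_mass_adjustment(one$peptide, d$enrichment, exact = TRUE)
  expect_equal(one$observed_mass,
               monoisotopic_mass(one$peptide) + shift,
               tolerance = 1e-4 * one$observed_mass)
})

test_that("plug genes carry the configured share of true male spectra", {
  fx <- generate_proteome(seed = 1)
  plug <- fx$proteins$gene_id[fx$proteins$origin == "male_plug"]
  plug_peps <- unique(unlist(lapply(
    fx$proteins$sequence[fx$proteins$gene_id %in% plug],
    seminalMS:::.detectable_peptides)))
  male_peps <- unique(unlist(lapply(
    fx$proteins$sequence[fx$proteins$origin %in%
                           c("male_plug", "male_seminal")],
    seminalMS:::.detectable_peptides)))
  shares <- vapply(1:20, function(s) {
    psms <- psm_bind(simulate_experiment(fx, default_design(meanlog = log(60)),
                                         seed = s))
    true_male <- psms[psms$match_truth == "true" &
                        psms$peptide %in% male_peps, ]
    mean(true_male$peptide %in% plug_peps)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.37), 0.05)
})

test_that("evolution tables encode selection truth and QC violations", {
  evo <- generate_evolution_table(300, fraction_selected = 0.2, effect = 3,
                                  seed = 9)
  expect_equal(nrow(evo$orthologs), 300)
  expect_equal(nrow(evo$fits), 300)
  # nested-model likelihood ordering
  expect_true(all(evo$fits$lnL_M8 >= evo$fits$lnL_M7))
  expect_true(all(evo$fits$lnL_M8 >= evo$fits$lnL_M8a))
  expect_true(all(evo$fits$prop_extra >= 0 & evo$fits$prop_extra <= 1))
  # stated QC violations actually violate the rules
  tr <- merge(evo$truth, evo$orthologs, by = "gene_id")
  expect_true(all(tr$aligned_codons[tr$qc_violation == "codons"] < 100))
  expect_true(all(tr$dN[tr$qc_violation == "dN"] > 1))
  expect_true(all(tr$dS[tr$qc_violation == "dS"] >= 0.381))
  expect_gt(sum(tr$qc_violation != ""), 0)
  # empty case
  evo0 <- generate_evolution_table(0)
  expect_equal(nrow(evo0$orthologs), 0)
  expect_equal(nrow(evo0$fits), 0)
})

test_that("PSM tables round-trip through TSV", {
  fx <- generate_proteome(n_male = 5, n_female = 5, n_plug = 2, seed = 4)
  psms <- psm_bind(simulate_experiment(
    fx, default_design(meanlog = log(10)), seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_psm_tsv(psms, f)
  back <- read_psm_tsv(f)
  expect_equal(back$peptide, psms$peptide)
  expect_equal(back$observed_mass, psms$observed_mass, tolerance = 1e-9)
  expect_equal(back$is_decoy, psms$is_decoy)
})
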