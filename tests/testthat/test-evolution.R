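test_that("NG86 dN/dS handles synonymous, nonsynonymous and identical pairs", {
  same <- ng86_dnds("ATGAAA", "ATGAAA")
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_false(same$omega_defined)

  # single nonsynonymous difference, hand-computed:
  # TTT (Phe) vs TTA (Leu): S = (1/3 + 2/3)/2 = 0.5, N = 2.5,
  # pN = 1/2.5 = 0.4 -> dN = -0.75 ln(1 - 1.6/3) = 0.5716053; dS = 0
  res <- ng86_dnds("TTT", "TTA")
  expect_equal(res$S_sites, 0.5)
  expect_equal(res$N_sites, 2.5)
  expect_equal(res$dN, 0.5716053, tolerance = 1e-6)
  expect_equal(res$dS, 0)
  expect_false(res$omega_defined)

  # purely synonymous difference over a longer stretch
  res2 <- ng86_dnds("GGAAAATTT", "GGGAAATTT")
  expect_equal(res2$dN, 0)
  expect_gt(res2$dS, 0)

  expect_error(ng86_dnds("ATG", "ATGAAA"), "equal length")
  expect_error(ng86_dnds("TAAATG", "TAGATG"), "stop")
})

test_that("NG86 matches an independent pathway-enumeration oracle", {
  gc <- oracle_codon_table()
  set.seed(31)
  codons <- names(gc)[gc != "*"]
  for (trial in 1:30) {
    c1 <- sample(codons, 3); c2 <- sample(codons, 3)
    s1 <- paste(c1, collapse = ""); s2 <- paste(c2, collapse = "")
    res <- ng86_dnds(s1, s2)
    S_o <- (sum(vapply(c1, oracle_syn_sites, numeric(1), gc = gc)) +
              sum(vapply(c2, oracle_syn_sites, numeric(1), gc = gc))) / 2
    d_o <- rowSums(vapply(1:3, function(i) {
      oracle_pathway_diffs(c1[i], c2[i], gc)
    }, numeric(2)))
    expect_equal(res$S_sites, S_o, tolerance = 1e-9)
    expect_equal(res$S_diffs, d_o[1], tolerance = 1e-9)
    expect_equal(res$N_diffs, d_o[2], tolerance = 1e-9)
    # symmetry
    rev <- ng86_dnds(s2, s1)
    expect_equal(res$S_diffs, rev$S_diffs, tolerance = 1e-12)
    expect_equal(res$N_sites, rev$N_sites, tolerance = 1e-12)
  }
})

test_that("pairwise QC applies the printed boundary semantics", {
  recs <- data.frame(
    gene_id = c("short", "fast_dN", "boundary_dN", "boundary_dS", "ok"),
    aligned_codons = c(99, 150, 150, 150, 150),
    dN = c(0.1, 1.5, 1.0, 0.1, 0.1),
    dS = c(0.2, 0.2, 0.2, 0.381, 0.2)
  )
  res <- pairwise_qc(recs)
  expect_setequal(res$kept$gene_id, c("boundary_dN", "ok"))
  expect_equal(res$removed$reason[res$removed$gene_id == "short"], "codons")
  expect_equal(res$removed$reason[res$removed$gene_id == "fast_dN"], "dN")
  expect_equal(res$removed$reason[res$removed$gene_id == "boundary_dS"], "dS")
  expect_error(pairwise_qc(transform(recs, dN = -dN)), "negative")
})

test_that("five-species QC removes genes exceeding twice the genome median", {
  fits <- data.frame(gene_id = c("a", "b", "c"),
                     pairwise_dS_max_ratio = c(2.1, 2.0, 0.5))
  res <- five_species_qc(fits)
  expect_setequal(res$kept$gene_id, c("b", "c"))  # exactly 2x is kept
  expect_equal(res$removed$gene_id, "a")
})

test_that("likelihood-ratio p-values track the chi-square tail", {
  expect_equal(lrt_pvalue(0, 0, 1)$p_value, 1)
  expect_lt(lrt_pvalue(-100, -100 + 29.8 / 2, 2)$p_value, 1e-6)
  expect_lt(lrt_pvalue(-100, -100 + 9.81 / 2, 2)$p_value, 0.01)
  expect_equal(lrt_pvalue(-50, -50 + 5, 2)$two_delta_L, 10)
  # strictly decreasing in the statistic; p(0) = 1
  p <- vapply(c(0, 1, 5, 10, 20), function(g) {
    lrt_pvalue(0, g / 2, 2)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_error(lrt_pvalue(0, 1, 0), "df")
  expect_error(lrt_pvalue(0, -1, 1), "below null")
  expect_message(lrt_pvalue(0, -1e-8, 1), "clamped")
})

test_that("the five-criterion verdict requires every criterion", {
  base <- data.frame(
    gene_id = "lactotransferrin_like", lnL_M7 = -5000,
    lnL_M8 = -5000 + 29.8 / 2, lnL_M8a = -5000 + 29.8 / 2 - 22.9 / 2,
    omega_extra = 3.8, prop_extra = 0.049, fel_sites = 2L,
    stringsAsFactors = FALSE
  )
  expect_true(selection_verdict(base)$selected)
  # each criterion individually broken
  fail3 <- transform(base, omega_extra = 1.05)
  expect_false(selection_verdict(fail3)$selected)
  expect_false(selection_verdict(fail3)$c3)
  fail4 <- transform(base, prop_extra = 0.005)
  expect_false(selection_verdict(fail4)$selected)
  fail5 <- transform(base, fel_sites = 0L)
  expect_false(selection_verdict(fail5)$selected)
  fail1 <- transform(base, lnL_M8 = lnL_M7 + 4 / 2,
                     lnL_M8a = lnL_M7 + 4 / 2 - 22.9 / 2)
  expect_false(selection_verdict(fail1)$c1)
  # boundary: omega_extra exactly 1.1 fails (strict), prop exactly 1% passes
  expect_false(selection_verdict(transform(base, omega_extra = 1.1))$c3)
  expect_true(selection_verdict(transform(base, prop_extra = 0.01))$c4)
  expect_error(selection_verdict(base[, -2]), "missing")
})

test_that("verdict recovers simulated selection with high recall and low", {
  # type-I error on the generator's truth labels
  null <- generate_evolution_table(1000, fraction_selected = 0, seed = 17)
  v0 <- selection_verdict(null$fits)
  expect_lte(mean(v0$selected), 0.01)

  pos <- generate_evolution_table(200, fraction_selected = 1, effect = 4,
                                  seed = 18)
  v1 <- selection_verdict(pos$fits)
  expect_gte(mean(v1$selected), 0.95)
})

test_that("rank-sum statistic follows the pair-counting convention", {
  res <- wilcoxon_rank_sum(c(3, 4), c(1, 2))
  expect_equal(res$W, 4)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-9)
  expect_equal(wilcoxon_rank_sum(1, 1)$W, 0.5)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # agreement with full enumeration on small tie-free samples
  set.seed(5)
  for (trial in 1:15) {
    x <- sample(seq(0.1, 20, by = 0.1), sample(3:6, 1))
    y <- sample(setdiff(seq(0.1, 20, by = 0.1), x), sample(3:6, 1))
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$W, sum(outer(x, y, ">")))
    expect_equal(res$p_value, oracle_wilcoxon_two_sided(x, y),
                 tolerance = 1e-9)
  }
})

test_that("exact rank-sum p-values are super-uniform under the null", {
  # full enumeration for n = m = 4: the test's size never exceeds nominal
  vals <- c(1.3, 2.7, 3.1, 4.9, 5.2, 6.8, 7.4, 8.6)
  idx <- utils::combn(8, 4)
  pvals <- apply(idx, 2, function(ii) {
    wilcoxon_rank_sum(vals[ii], vals[-ii])$p_value
  })
  for (alpha in c(0.05, 0.1, 0.2, 0.5)) {
    expect_lte(mean(pvals <= alpha), alpha)
  }
})

test_that("a simulated location shift is detected reliably", {
  set.seed(77)
  hits <- vapply(1:100, function(i) {
    x <- rnorm(50, 1); y <- rnorm(50, 0)
    wilcoxon_rank_sum(x, y)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Fisher's exact test matches enumeration over all small tables", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_lt(fisher_exact_2x2(29, 25, 303, 126), 0.02)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  for (a in 0:3) for (b in 0:3) for (c in 0:2) for (d in 0:2) {
    if (a + b + c + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d),
                 oracle_fisher_two_sided(a, b, c, d), tolerance = 1e-7)
  }
})
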