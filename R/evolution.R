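# Evolutionary-rate stage: a Nei-Gojobori (1986) pathway-counting dN/dS
# estimator for synthetic testing, pairwise and five-species quality-control
# filters, likelihood-ratio tests on M7/M8/M8a site-model fits, the
# five-criterion recurrent-positive-selection verdict, and the nonparametric
# comparative statistics.

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.codon_split <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("sequence length must be a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- .GENETIC_CODE[codons]
  if (any(is.na(aa))) stop("invalid codon: ", codons[which(is.na(aa))[1L]])
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  }
  codons
}

# Synonymous site count of one codon: over the 9 single-nucleotide mutants,
# the fraction per position encoding the same amino acid. Mutations to stop
# codons count as nonsynonymous.
.syn_sites <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  nts <- c("T", "C", "A", "G")
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (nt in setdiff(nts, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (.GENETIC_CODE[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous step counts over all substitution
# pathways between two codons (equal pathway weights). Pathways passing
# through stop codons are excluded; if every pathway is blocked they are
# all used.
.pathway_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(pos) else {
    if (d == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  walk <- function(order) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.GENETIC_CODE[[nxt]] == "*") blocked <- TRUE
      if (.GENETIC_CODE[[nxt]] == .GENETIC_CODE[[cur]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(syn = mean(res["syn", ok]), nonsyn = mean(res["nonsyn", ok]))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (equal-weight averaging over substitution
#' pathways for multi-substitution codons), then applies the Jukes-Cantor
#' multiple-hit correction. When `dS` is zero, omega is undefined and
#' returned as `NA` with `omega_defined = FALSE`.
#'
#' @param cds1,cds2 Aligned coding sequences (equal length, multiple of 3,
#'   no internal stop codons).
#' @return List with `dN`, `dS`, `omega`, `omega_defined`, plus the
#'   underlying site and difference counts (`N_sites`, `S_sites`, `N_diffs`,
#'   `S_diffs`).
#' @export
ng86_dnds <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2)) stop("sequences must have equal length")
  cod1 <- .codon_split(cds1)
  cod2 <- .codon_split(cds2)
  S1 <- sum(vapply(cod1, .syn_sites, numeric(1)))
  S2 <- sum(vapply(cod2, .syn_sites, numeric(1)))
  S <- (S1 + S2) / 2
  N <- 3 * length(cod1) - S
  diffs <- vapply(seq_along(cod1), function(i) {
    .pathway_diffs(cod1[i], cod2[i])
  }, numeric(2))
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  defined <- !is.na(dS) && dS > 0 && !is.na(dN)
  list(
    dN = dN, dS = dS,
    omega = if (defined) dN / dS else NA_real_,
    omega_defined = defined,
    N_sites = N, S_sites = S, N_diffs = Nd, S_diffs = Sd
  )
}

#' Pairwise ortholog quality control
#'
#' Removes genes with fewer than 100 aligned codons, dN above 1 (dN equal to
#' 1 is kept), or dS at or above 0.381, with the boundary semantics exactly
#' as stated.
#'
#' @param records data.frame with columns `gene_id`, `aligned_codons`, `dN`,
#'   `dS`.
#' @return List with `kept` and `removed` (the latter with a `reason`
#'   column; the first failing rule in the order codons, dN, dS).
#' @export
pairwise_qc <- function(records) {
  req <- c("gene_id", "aligned_codons", "dN", "dS")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (any(records$dN < 0, na.rm = TRUE) || any(records$dS < 0, na.rm = TRUE)) {
    stop("negative substitution rates")
  }
  reason <- rep(NA_character_, nrow(records))
  reason[records$aligned_codons < 100] <- "codons"
  reason[is.na(reason) & records$dN > 1] <- "dN"
  reason[is.na(reason) & records$dS >= 0.381] <- "dS"
  removed <- records[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Five-species divergence quality control
#'
#' Excludes genes whose maximum pairwise dS across the species combinations
#' exceeds twice the genome median (a ratio of exactly 2 is kept).
#'
#' @param fits Site-model fit data.frame with column `pairwise_dS_max_ratio`
#'   (max pairwise dS over the genome median).
#' @return List with `kept` and `removed`.
#' @export
five_species_qc <- function(fits) {
  if (!"pairwise_dS_max_ratio" %in% names(fits)) {
    stop("fits must have column 'pairwise_dS_max_ratio'")
  }
  drop <- fits$pairwise_dS_max_ratio > 2
  list(
    kept = fits[!drop, , drop = FALSE],
    removed = fits[drop, , drop = FALSE]
  )
}

#' Likelihood-ratio test between nested site models
#'
#' `2dL = 2 (lnL_alt - lnL_null)` compared to a chi-square upper tail with
#' `df` degrees of freedom (M7 vs M8: df = 2; M8a vs M8: df = 1; a plain
#' chi-square null is used rather than a boundary mixture, which is
#' conservative). Small negative gaps from optimizer noise (within 1e-6) are
#' clamped to zero.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the nested and the richer
#'   model.
#' @param df Degrees of freedom.
#' @return List with `two_delta_L` and `p_value`.
#' @export
lrt_pvalue <- function(lnL_null, lnL_alt, df) {
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("'df' must be >= 1")
  gap <- lnL_alt - lnL_null
  if (gap < -1e-6) {
    stop("alternative log-likelihood below null beyond tolerance")
  }
  if (gap < 0) {
    message("negative likelihood gap ", signif(gap, 3), " clamped to 0")
    gap <- 0
  }
  two_dL <- 2 * gap
  list(
    two_delta_L = two_dL,
    p_value = stats::pchisq(two_dL, df = df, lower.tail = FALSE)
  )
}

#' Five-criterion verdict for recurrent positive selection
#'
#' A gene is called as having a history of recurrent adaptive evolution when
#' all five criteria hold: (1) M8 fits significantly better than M7
#' (df 2, p below `alpha1`); (2) M8 fits significantly better than M8a
#' (df 1, p below `alpha2`); (3) the additional dN/dS class estimated by M8
#' exceeds `omega_min`; (4) at least `prop_min` of codons belong to that
#' class; (5) FEL analysis finds at least `fel_min` positively selected
#' codons.
#'
#' @param fits Site-model fit data.frame (columns `gene_id`, `lnL_M7`,
#'   `lnL_M8`, `lnL_M8a`, `omega_extra`, `prop_extra`, `fel_sites`).
#' @param alpha1,alpha2 LRT significance levels (defaults 0.01).
#' @param omega_min Minimum extra-class omega (default 1.1, strict).
#' @param prop_min Minimum extra-class codon proportion (default 0.01,
#'   inclusive).
#' @param fel_min Minimum FEL site count (default 1, inclusive).
#' @return data.frame `gene_id`, `c1`..`c5`, `selected`.
#' @export
selection_verdict <- function(fits, alpha1 = 0.01, alpha2 = 0.01,
                              omega_min = 1.1, prop_min = 0.01,
                              fel_min = 1L) {
  req <- c("gene_id", "lnL_M7", "lnL_M8", "lnL_M8a", "omega_extra",
           "prop_extra", "fel_sites")
  miss <- setdiff(req, names(fits))
  if (length(miss)) stop("fits missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(fits$lnL_M7) | is.na(fits$lnL_M8) | is.na(fits$lnL_M8a))) {
    stop("missing log-likelihoods")
  }
  p1 <- stats::pchisq(2 * (fits$lnL_M8 - fits$lnL_M7), df = 2,
                      lower.tail = FALSE)
  p2 <- stats::pchisq(2 * (fits$lnL_M8 - fits$lnL_M8a), df = 1,
                      lower.tail = FALSE)
  c1 <- p1 < alpha1
  c2 <- p2 < alpha2
  c3 <- fits$omega_extra > omega_min
  c4 <- fits$prop_extra >= prop_min
  c5 <- fits$fel_sites >= fel_min
  data.frame(
    gene_id = fits$gene_id, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
    selected = c1 & c2 & c3 & c4 & c5, stringsAsFactors = FALSE
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' `W` is the Mann-Whitney statistic of the first sample: the number of
#' pairs `(x_i, y_j)` with `x_i > y_j`, counting ties as one half (the
#' convention under which rank-sum software reports statistics like
#' W = 7,336). The two-sided p-value is exact (permutation null) when both
#' samples are small (`min(n, m) <= 8`) and tie-free, and uses the normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric vectors.
#' @return List with `W` and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  W <- sum(vapply(x, function(xi) {
    sum(xi > y) + 0.5 * sum(xi == y)
  }, numeric(1)))
  pooled <- c(x, y)
  if (all(pooled == pooled[1L])) {
    # fully tied data carry no ordering information
    return(list(W = W, p_value = 1))
  }
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- !has_ties && min(length(x), length(y)) <= 8L
  p <- suppressWarnings(stats::wilcox.test(
    x, y, exact = use_exact, correct = TRUE
  )$p.value)
  list(W = W, p_value = min(p, 1))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise (`a`,`b` top row).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(29, 25, 303, 126)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}
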