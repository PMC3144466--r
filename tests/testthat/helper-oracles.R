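# Independent oracles used to check package computations. These are written
# as plain brute-force enumerations, deliberately sharing no code with the
# implementations they check.

# Full isotopologue distribution by exhaustive multinomial expansion over
# per-element isotope assignments (feasible for small atom counts). Returns
# intensities over nominal offsets 0..(n_peaks-1), renormalized.
oracle_isotope_distribution <- function(comp, n15_fraction, n_peaks) {
  iso <- list(
    C = list(offset = c(0, 1), p = c(0.9893, 0.0107)),
    H = list(offset = c(0, 1), p = c(0.999885, 0.000115)),
    N = list(offset = c(0, 1), p = c(1 - n15_fraction, n15_fraction)),
    O = list(offset = c(0, 1, 2), p = c(0.99757, 0.00038, 0.00205)),
    S = list(offset = c(0, 1, 2, 4), p = c(0.9493, 0.0076, 0.0429, 0.0002))
  )
  # compositions of n atoms over k isotope slots
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, ncol = 1L))
    out <- NULL
    for (i in 0:n) {
      rest <- compositions(n - i, k - 1L)
      out <- rbind(out, cbind(i, rest))
    }
    out
  }
  dist <- c(1)  # index = offset + 1
  for (el in names(comp)) {
    n <- comp[[el]]
    if (is.na(n) || n == 0) next
    tab <- iso[[el]]
    k <- length(tab$p)
    cc <- compositions(n, k)
    el_dist <- numeric(sum(tab$offset * 0) + n * max(tab$offset) + 1L)
    for (r in seq_len(nrow(cc))) {
      counts <- cc[r, ]
      off <- sum(counts * tab$offset)
      el_dist[off + 1L] <- el_dist[off + 1L] +
        exp(lfactorial(n) - sum(lfactorial(counts)) +
              sum(counts * log(tab$p)))
    }
    new <- numeric(length(dist) + length(el_dist) - 1L)
    for (i in seq_along(dist)) {
      for (j in seq_along(el_dist)) {
        new[i + j - 1L] <- new[i + j - 1L] + dist[i] * el_dist[j]
      }
    }
    dist <- new
  }
  if (length(dist) < n_peaks) dist <- c(dist, numeric(n_peaks - length(dist)))
  head_part <- dist[seq_len(n_peaks)]
  head_part / sum(head_part)
}

# Exact hypergeometric upper tail by direct summation of choose() ratios.
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher p by enumeration of all tables with the observed margins
# (point-probability rule, with the conventional relative tolerance).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all label assignments.
oracle_wilcoxon_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  w_of <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  w_obs <- w_of(x, y)
  ws <- apply(idx, 2, function(ii) w_of(pooled[ii], pooled[-ii]))
  mu <- n * (length(pooled) - n) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Protein inference by direct set logic over an explicit peptide->genes map.
oracle_infer <- function(peptides, pep2genes) {
  genes <- sort(unique(unlist(pep2genes)))
  out <- list(identified = character(0), ambiguous = character(0))
  for (g in genes) {
    peps <- peptides[vapply(peptides, function(p) g %in% pep2genes[[p]],
                            logical(1))]
    peps <- unique(peps)
    if (length(peps) < 2) next
    n_unique <- sum(vapply(peps, function(p) length(pep2genes[[p]]) == 1L,
                           logical(1)))
    if (n_unique >= 1) out$identified <- c(out$identified, g)
    else out$ambiguous <- c(out$ambiguous, g)
  }
  out
}

# NG86 pieces recomputed from Biostrings' genetic code (independent of the
# package's hard-coded table): synonymous sites of a codon and the
# pathway-averaged difference counts.
oracle_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

oracle_syn_sites <- function(codon, gc = oracle_codon_table()) {
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("T", "C", "A", "G"), substr(codon, pos, pos))) {
      mut <- codon; substr(mut, pos, pos) <- nt
      if (gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracle_pathway_diffs <- function(c1, c2, gc = oracle_codon_table()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    m <- as.matrix(expand.grid(rep(list(seq_along(pos)), length(pos))))
    m <- m[apply(m, 1, function(r) length(unique(r)) == length(pos)), ,
           drop = FALSE]
    lapply(seq_len(nrow(m)), function(i) pos[m[i, ]])
  }
  res <- t(vapply(perms, function(ord) {
    cur <- c1; syn <- 0; non <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non, blocked)
  }, numeric(3)))
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(mean(res[ok, 1]), mean(res[ok, 2]))
}

# Small deterministic PSM table builder.
make_psms <- function(target_scores, decoy_scores) {
  data.frame(
    score = c(target_scores, decoy_scores),
    is_decoy = rep(c(FALSE, TRUE), c(length(target_scores),
                                     length(decoy_scores))),
    peptide = paste0("PEP", seq_along(c(target_scores, decoy_scores))),
    stringsAsFactors = FALSE
  )
}
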