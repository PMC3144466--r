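# Spectral-count quantification: normalized spectral abundance factors,
# transcript-length handling, replicate discovery curves and the
# first-vs-later-replicate abundance comparison.

#' Normalized spectral abundance factor (NSAF)
#'
#' For each gene, the spectral abundance factor is its (fractional) spectral
#' count divided by its protein length; NSAF divides this by the sum of
#' abundance factors over all genes, so NSAF lies in \[0, 1\] and sums to 1
#' across the identified set. Counts are conventionally summed across the
#' biological samples of the experiment before calling this function;
#' restricting the counts to one sample gives per-sample NSAF.
#'
#' @param counts Named numeric vector gene_id -> fractional spectral count.
#' @param lengths Named numeric vector gene_id -> length in residues (for
#'   genes with several transcripts, an effective length such as the median,
#'   see [effective_length()]).
#' @return data.frame `gene_id`, `spectral_count`, `length`, `saf`, `nsaf`,
#'   `rank` (1 = most abundant), sorted by decreasing NSAF.
#' @export
#' @examples
#' nsaf(c(A = 10, B = 10), c(A = 100, B = 200))
nsaf <- function(counts, lengths) {
  if (!length(counts)) stop("no counts supplied")
  genes <- names(counts)
  if (is.null(genes)) stop("'counts' must be named by gene")
  len <- lengths[genes]
  bad <- genes[is.na(len) | len <= 0]
  if (length(bad)) {
    stop("missing or non-positive length for gene: ", bad[1L])
  }
  saf <- counts / len
  out <- data.frame(
    gene_id = genes,
    spectral_count = unname(counts),
    length = unname(len),
    saf = unname(saf),
    nsaf = unname(saf / sum(saf)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$nsaf, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Effective length for genes with alternative transcripts
#'
#' @param transcript_lengths Numeric vector of transcript lengths (residues).
#' @param rule One of `"median"` (default; even-length lists use the mean of
#'   the central pair), `"shortest"`, `"longest"`, `"random"`.
#' @param seed Seed used when `rule = "random"`.
#' @return Single effective length.
#' @export
effective_length <- function(transcript_lengths,
                             rule = c("median", "shortest", "longest",
                                      "random"),
                             seed = 1L) {
  if (!length(transcript_lengths)) stop("empty transcript length list")
  rule <- match.arg(rule)
  switch(rule,
    median = stats::median(transcript_lengths),
    shortest = min(transcript_lengths),
    longest = max(transcript_lengths),
    random = .with_seed(seed, sample(transcript_lengths, 1L))
  )
}

#' Cumulative gene discovery across technical replicates
#'
#' @param replicate_sets List of character vectors, the genes identified in
#'   each technical replicate, in run order.
#' @return data.frame `replicate`, `n_new`, `cumulative`.
#' @export
#' @examples
#' discovery_curve(list(c("A", "B"), c("B", "C"), "C"))
discovery_curve <- function(replicate_sets) {
  if (!length(replicate_sets)) stop("no replicates supplied")
  seen <- character(0)
  n_new <- integer(length(replicate_sets))
  cumulative <- integer(length(replicate_sets))
  for (r in seq_along(replicate_sets)) {
    new <- setdiff(unique(replicate_sets[[r]]), seen)
    seen <- c(seen, new)
    n_new[r] <- length(new)
    cumulative[r] <- length(seen)
  }
  data.frame(replicate = seq_along(replicate_sets), n_new = n_new,
             cumulative = cumulative)
}

#' Arcsine-square-root transform of NSAF values
#'
#' Values are clipped to \[0, 1\] before the transform to guard floating-point
#' excursions at the boundary.
#'
#' @param x NSAF values.
#' @return Transformed values in radians.
#' @export
arcsin_sqrt <- function(x) {
  asin(sqrt(pmin(pmax(x, 0), 1)))
}

#' Compare NSAF of first-replicate vs later-discovered genes
#'
#' Genes found in the first technical replicate are expected to be more
#' abundant than genes only discovered in later replicates. NSAF values are
#' arcsine-square-root transformed and compared with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param first_genes,later_genes Disjoint character vectors of gene ids.
#' @param nsaf_table NSAF data.frame from [nsaf()].
#' @return List with `first` / `later` transformed values, group medians,
#'   `W` and `p_value`.
#' @export
first_vs_later_nsaf <- function(first_genes, later_genes, nsaf_table) {
  if (!length(first_genes) || !length(later_genes)) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(first_genes, later_genes))) {
    stop("groups must be disjoint")
  }
  v <- stats::setNames(nsaf_table$nsaf, nsaf_table$gene_id)
  miss <- setdiff(c(first_genes, later_genes), names(v))
  if (length(miss)) stop("no NSAF value for gene: ", miss[1L])
  x <- arcsin_sqrt(v[first_genes])
  y <- arcsin_sqrt(v[later_genes])
  test <- wilcoxon_rank_sum(x, y)
  list(
    first = x, later = y,
    median_first = stats::median(x), median_later = stats::median(y),
    W = test$W, p_value = test$p_value
  )
}
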