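# Term-for-term functional overrepresentation with Bonferroni correction.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the number of annotated genes in a random draw of
#' `n` genes from a population of `N` genes of which `K` are annotated — the
#' term-for-term enrichment statistic.
#'
#' @param N Population size.
#' @param K Annotated genes in the population.
#' @param n Study-set size.
#' @param k Annotated genes in the study set.
#' @return Upper-tail probability.
#' @export
#' @examples
#' hypergeometric_tail(10, 5, 5, 5)  # 1 / choose(10, 5)
hypergeometric_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("counts must be non-negative integers")
  }
  if (K > N || n > N || k > n || k > K) {
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term-for-term overrepresentation test
#'
#' Tests every annotation term carried by at least one study gene for
#' overrepresentation in the study set relative to the population, using the
#' upper-tail hypergeometric probability, and applies a Bonferroni correction
#' with multiplier equal to the number of terms tested. Following the
#' convention of genome-annotation enrichment tools, the population is
#' restricted to annotated genes (study genes without any annotation drop out
#' of the study count as well).
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population gene ids.
#' @param annotations data.frame with columns `gene_id` and `term_id` (one
#'   pair per row, pre-propagated if ontology propagation is wanted).
#' @return data.frame `term_id`, `K`, `N`, `k`, `n`, `p_raw`, `p_bonferroni`,
#'   sorted by `p_raw`.
#' @export
term_for_term <- function(study, population, annotations) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population)) {
    stop("study set must be a subset of the population")
  }
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "term_id") %in% names(annotations))) {
    stop("'annotations' must have columns 'gene_id' and 'term_id'")
  }
  ann <- unique(annotations[annotations$gene_id %in% population,
                            c("gene_id", "term_id")])
  annotated <- unique(ann$gene_id)
  N <- length(annotated)
  study_ann <- intersect(study, annotated)
  n <- length(study_ann)
  terms <- unique(ann$term_id[ann$gene_id %in% study_ann])
  if (!length(terms)) {
    return(data.frame(
      term_id = character(0), K = integer(0), N = integer(0),
      k = integer(0), n = integer(0), p_raw = numeric(0),
      p_bonferroni = numeric(0), stringsAsFactors = FALSE
    ))
  }
  m <- length(terms)
  rows <- lapply(terms, function(tm) {
    genes_tm <- ann$gene_id[ann$term_id == tm]
    K <- length(unique(genes_tm))
    k <- length(intersect(study_ann, genes_tm))
    p <- hypergeometric_tail(N, K, n, k)
    data.frame(
      term_id = tm, K = K, N = N, k = k, n = n, p_raw = p,
      p_bonferroni = min(1, m * p), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
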