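# Target-decoy identification machinery: decoy databases, mass-window
# matching in natural and labeled modes, per-spectrum FDR filtering,
# peptide-to-gene mapping, two-peptide/one-unique protein inference,
# fractional spectral counting, and the three-criteria filter for
# mating-induced female proteins.

#' Shuffled decoy database
#'
#' One decoy per target protein, obtained by randomly shuffling the target
#' sequence (identical length and residue multiset), with gene ids prefixed
#' `DECOY_`.
#'
#' @param fixture A `proteome_fixture`.
#' @param seed Integer seed.
#' @return A `proteome_fixture` of decoy proteins (origin `"decoy"`).
#' @export
decoy_database <- function(fixture, seed = 1L) {
  stopifnot(inherits(fixture, "proteome_fixture"))
  if (nrow(fixture$proteins) == 0L) stop("fixture is empty")
  .with_seed(seed, {
    p <- fixture$proteins
    shuffled <- vapply(p$sequence, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    ids <- paste0("DECOY_", p$gene_id)
    fam <- paste0("DECOY_", fixture$family_map[p$gene_id])
    names(fam) <- ids
    structure(
      list(
        proteins = data.frame(
          gene_id = ids, origin = "decoy", sequence = shuffled,
          stringsAsFactors = FALSE
        ),
        family_map = fam
      ),
      class = "proteome_fixture"
    )
  })
}

#' Per-spectrum target-decoy FDR filter
#'
#' Finds the lowest score threshold `s` such that
#' `(# decoys with score >= s) / (# targets with score >= s) <= fdr`, and
#' accepts all target PSMs with score at or above it (ties at the threshold
#' are accepted). Candidate thresholds are the observed scores.
#'
#' @param psms PSM data.frame with columns `score` and `is_decoy`.
#' @param fdr Nominal per-spectrum FDR in (0, 1).
#' @return List with `accepted` (target rows passing), `threshold`,
#'   `n_targets`, `n_decoys` (counts at the threshold) and `est_fdr`.
#'   If no threshold attains the FDR, `accepted` is empty and `threshold`
#'   is `Inf`.
#' @export
filter_psms_fdr <- function(psms, fdr = 0.01) {
  if (!is.data.frame(psms) || !all(c("score", "is_decoy") %in% names(psms))) {
    stop("'psms' must have columns 'score' and 'is_decoy'")
  }
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) stop("'fdr' must be in (0, 1)")
  if (!any(psms$is_decoy)) {
    stop("no decoy PSMs present; FDR is undefined without decoys")
  }
  if (any(!is.finite(psms$score))) stop("scores must be finite")
  target_scores <- psms$score[!psms$is_decoy]
  decoy_scores <- psms$score[psms$is_decoy]
  thresholds <- sort(unique(psms$score))
  for (s in thresholds) {
    n_t <- sum(target_scores >= s)
    n_d <- sum(decoy_scores >= s)
    if (n_t > 0L && n_d / n_t <= fdr) {
      return(list(
        accepted = psms[!psms$is_decoy & psms$score >= s, , drop = FALSE],
        threshold = s, n_targets = n_t, n_decoys = n_d,
        est_fdr = n_d / n_t
      ))
    }
  }
  list(
    accepted = psms[integer(0), , drop = FALSE],
    threshold = Inf, n_targets = 0L, n_decoys = 0L, est_fdr = NA_real_
  )
}

#' Build a peptide mass index for mass-window matching
#'
#' @param fixture A `proteome_fixture` (targets, optionally concatenated with
#'   a decoy fixture via [concat_fixtures()]).
#' @param max_missed Missed cleavages for the digest.
#' @param min_len,max_len Detectability window in residues.
#' @return data.frame `peptide`, `mass`, `n_nitrogen`.
#' @export
peptide_index <- function(fixture, max_missed = 0L, min_len = 6L,
                          max_len = 30L) {
  stopifnot(inherits(fixture, "proteome_fixture"))
  peps <- unique(unlist(lapply(
    fixture$proteins$sequence, .detectable_peptides,
    max_missed = max_missed, min_len = min_len, max_len = max_len
  )))
  data.frame(
    peptide = peps,
    mass = vapply(peps, function(x) monoisotopic_mass(x), numeric(1),
                  USE.NAMES = FALSE),
    n_nitrogen = vapply(peps, peptide_nitrogens, integer(1),
                        USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Concatenate target and decoy fixtures
#' @param a,b `proteome_fixture` objects.
#' @return A `proteome_fixture`.
#' @export
concat_fixtures <- function(a, b) {
  structure(
    list(
      proteins = rbind(a$proteins, b$proteins),
      family_map = c(a$family_map, b$family_map)
    ),
    class = "proteome_fixture"
  )
}

#' Labeled-mode mass matching
#'
#' Returns index peptides whose theoretical mass, adjusted for 15N labeling
#' at the given incorporation, lies within `tol_ppm` of the query mass.
#' The default adjustment is the `incorporation`-Daltons-per-nitrogen search
#' approximation; `exact = TRUE` uses the physical 15N-14N mass difference.
#' With `incorporation = 0` this is ordinary natural-mode matching.
#'
#' @param query_mass Observed neutral mass in Da.
#' @param index Peptide index from [peptide_index()].
#' @param incorporation 15N incorporation assumed by the search.
#' @param tol_ppm Mass tolerance in parts per million.
#' @param exact Use the exact per-nitrogen mass shift.
#' @return Character vector of candidate peptides.
#' @export
match_labeled_mode <- function(query_mass, index, incorporation = 0.95,
                               tol_ppm = 10, exact = FALSE) {
  if (!is.data.frame(index) || nrow(index) == 0L) {
    stop("peptide index is empty")
  }
  if (incorporation < 0 || incorporation > 1) {
    stop("'incorporation' must be in [0, 1]")
  }
  per_n <- if (exact) incorporation * .N15_DELTA else incorporation
  expected <- index$mass + index$n_nitrogen * per_n
  index$peptide[abs(expected - query_mass) <= expected * tol_ppm * 1e-6]
}

#' Map peptides to genes
#'
#' Exact containment of each peptide in the tryptic peptide set of each gene;
#' `n_locations` is the number of distinct genes whose digest contains the
#' peptide (the operational reading of "regions in the genome" for a
#' protein-level database).
#'
#' @param peptides Character vector of peptides.
#' @param fixture A `proteome_fixture` of target proteins.
#' @param max_missed,min_len,max_len Digest parameters (must match the
#'   search).
#' @return data.frame `peptide`, `genes` (`;`-separated), `n_locations`.
#' @export
map_peptides <- function(peptides, fixture, max_missed = 0L, min_len = 1L,
                         max_len = Inf) {
  stopifnot(inherits(fixture, "proteome_fixture"))
  peptides <- unique(peptides)
  sets <- lapply(fixture$proteins$sequence, function(s) {
    p <- tryptic_digest(s, max_missed)
    unique(p[nchar(p) >= min_len & nchar(p) <= max_len])
  })
  names(sets) <- fixture$proteins$gene_id
  gene_of_pep <- new.env(parent = emptyenv())
  for (g in names(sets)) {
    for (pep in sets[[g]]) {
      assign(pep, c(if (exists(pep, envir = gene_of_pep))
        get(pep, envir = gene_of_pep), g), envir = gene_of_pep)
    }
  }
  genes <- lapply(peptides, function(pep) {
    if (exists(pep, envir = gene_of_pep)) get(pep, envir = gene_of_pep)
    else character(0)
  })
  data.frame(
    peptide = peptides,
    genes = vapply(genes, paste, character(1), collapse = ";"),
    n_locations = lengths(genes),
    stringsAsFactors = FALSE
  )
}

.mapping_list <- function(mapping) {
  g <- strsplit(mapping$genes, ";", fixed = TRUE)
  g[mapping$genes == ""] <- list(character(0))
  names(g) <- mapping$peptide
  g
}

#' Fractional spectral counts
#'
#' Each accepted PSM contributes `1 / n_locations` to every gene containing
#' its peptide, so a spectrum never counts more than once in total and the
#' sum of gene counts equals the number of accepted PSMs whose peptide maps
#' to at least one gene.
#'
#' @param accepted Accepted PSM data.frame (column `peptide`).
#' @param mapping Mapping from [map_peptides()].
#' @return Named numeric vector gene_id -> fractional count.
#' @export
fractional_counts <- function(accepted, mapping) {
  glist <- .mapping_list(mapping)
  counts <- new.env(parent = emptyenv())
  for (pep in accepted$peptide) {
    genes <- glist[[pep]]
    if (is.null(genes) || !length(genes)) next
    w <- 1 / length(genes)
    for (g in genes) {
      assign(g, w + if (exists(g, envir = counts)) get(g, envir = counts)
             else 0, envir = counts)
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) out <- structure(numeric(0), names = character(0))
  out[order(names(out))]
}

#' Protein (gene) inference
#'
#' A gene is identified when at least two distinct accepted peptides map to
#' it and at least one of them maps uniquely to that gene. Genes failing
#' only the uniqueness clause (two or more peptides, none unique) are
#' reported separately as ambiguous identifications.
#'
#' @param accepted Accepted PSM data.frame (column `peptide`).
#' @param mapping Mapping from [map_peptides()].
#' @return List with `identified` (data.frame `gene_id`, `n_peptides`,
#'   `n_unique_peptides`, `spectral_count`, `peptides`) and `ambiguous`
#'   (same columns).
#' @export
infer_genes <- function(accepted, mapping) {
  glist <- .mapping_list(mapping)
  missing <- setdiff(unique(accepted$peptide), names(glist))
  if (length(missing)) {
    stop("mapping does not cover accepted peptides: ", missing[1L])
  }
  counts <- fractional_counts(accepted, mapping)
  peps_by_gene <- list()
  for (pep in unique(accepted$peptide)) {
    genes <- glist[[pep]]
    for (g in genes) peps_by_gene[[g]] <- c(peps_by_gene[[g]], pep)
  }
  rows <- lapply(names(peps_by_gene), function(g) {
    peps <- unique(peps_by_gene[[g]])
    uniq <- vapply(peps, function(p) length(glist[[p]]) == 1L, logical(1))
    data.frame(
      gene_id = g,
      n_peptides = length(peps),
      n_unique_peptides = sum(uniq),
      spectral_count = unname(counts[g]),
      peptides = paste(sort(peps), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(
      gene_id = character(0), n_peptides = integer(0),
      n_unique_peptides = integer(0), spectral_count = numeric(0),
      peptides = character(0), stringsAsFactors = FALSE
    )
  }
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  identified <- tab[tab$n_peptides >= 2L & tab$n_unique_peptides >= 1L, ,
                    drop = FALSE]
  ambiguous <- tab[tab$n_peptides >= 2L & tab$n_unique_peptides == 0L, ,
                   drop = FALSE]
  rownames(identified) <- rownames(ambiguous) <- NULL
  list(identified = identified, ambiguous = ambiguous)
}

#' Filter for mating-induced female proteins
#'
#' Applies the three criteria for calling a labeled (female-derived) protein
#' induced by mating: (i) predicted secretion signal with probability above
#' `p_min` (missing probabilities fail the criterion and are logged),
#' (ii) not identified in the unmated 15N-labeled control, and (iii) not
#' identified as a male-derived seminal-fluid gene.
#'
#' @param labeled_ids Genes identified in labeled-mode searches.
#' @param secretion_prob Named numeric vector gene_id -> secretion
#'   probability.
#' @param unmated_ids Genes identified in the unmated control.
#' @param male_ids Genes identified as male-derived.
#' @param p_min Secretion-probability threshold (criterion i is `p > p_min`).
#' @return data.frame `gene_id`, `secretion_p`, `c1`, `c2`, `c3`, `induced`.
#' @export
female_induced_filter <- function(labeled_ids, secretion_prob, unmated_ids,
                                  male_ids, p_min = 0.90) {
  labeled_ids <- unique(labeled_ids)
  p <- secretion_prob[labeled_ids]
  names(p) <- labeled_ids
  n_missing <- sum(is.na(p))
  if (n_missing > 0L) {
    message(n_missing,
            " gene(s) lack secretion probabilities; treated as failing",
            " the secretion criterion")
  }
  c1 <- !is.na(p) & p > p_min
  c2 <- !(labeled_ids %in% unmated_ids)
  c3 <- !(labeled_ids %in% male_ids)
  data.frame(
    gene_id = labeled_ids,
    secretion_p = unname(p),
    c1 = unname(c1), c2 = c2, c3 = c3,
    induced = unname(c1) & c2 & c3,
    stringsAsFactors = FALSE
  )
}
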