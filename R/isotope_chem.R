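# Peptide elemental composition, monoisotopic mass, 15N mass arithmetic and
# theoretical isotope envelopes under arbitrary 15N enrichment.
#
# Envelopes are computed by convolving per-element isotopologue distributions.
# The nitrogen heavy-isotope probability is a free parameter, so the same code
# produces the natural-abundance template (15N at 0.003663) and the enriched
# template (e.g. 15N at 0.95) used to classify observed features as male
# (unlabeled) or female (labeled).

#' Elemental composition of a peptide
#'
#' Sums the residue formulas of a peptide and adds one water, giving counts of
#' C, H, N, O and S atoms.
#'
#' @param peptide Character scalar of standard one-letter residue codes.
#' @return Named integer vector with elements `C`, `H`, `N`, `O`, `S`.
#' @export
#' @examples
#' elemental_composition("GG")  # C4 H8 N2 O3
elemental_composition <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("'peptide' must be a non-empty character scalar")
  }
  residues <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% .AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf(
      "non-standard residue '%s' at position %d", residues[bad[1L]], bad[1L]
    ))
  }
  counts <- colSums(.RESIDUE_FORMULAS[residues, , drop = FALSE])
  counts[["H"]] <- counts[["H"]] + 2
  counts[["O"]] <- counts[["O"]] + 1
  storage.mode(counts) <- "integer"
  counts
}

#' Number of nitrogen atoms in a peptide
#'
#' @inheritParams elemental_composition
#' @return Integer nitrogen-atom count.
#' @export
peptide_nitrogens <- function(peptide) {
  elemental_composition(peptide)[["N"]]
}

.as_composition <- function(comp) {
  if (is.character(comp)) comp <- elemental_composition(comp)
  full <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  if (is.null(names(comp)) || !all(names(comp) %in% names(full))) {
    stop("composition must be a named vector with names among C, H, N, O, S")
  }
  if (any(comp < 0)) stop("element counts must be non-negative")
  full[names(comp)] <- as.integer(comp)
  full
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named count vector (as from [elemental_composition()]) or a
#'   peptide string.
#' @return Mass in Daltons (all-light-isotope species).
#' @export
#' @examples
#' monoisotopic_mass("GG")  # 132.0535
monoisotopic_mass <- function(comp) {
  comp <- .as_composition(comp)
  sum(comp * .MONO_MASS[names(comp)])
}

#' 15N mass adjustment of a peptide
#'
#' The mass shift applied when searching for metabolically labeled peptides.
#' The default reproduces the conventional search-engine approximation:
#' `incorporation` Daltons per nitrogen atom (2.85 Da for "AK" at 95%).
#' With `exact = TRUE` the physically exact shift is used instead,
#' `incorporation * 0.9970349` Da per nitrogen (the 15N-14N mass difference).
#'
#' @param peptide Peptide string.
#' @param incorporation Fraction of nitrogen atoms that are 15N, in \[0, 1\].
#' @param exact Use the exact 15N-14N mass difference instead of 1 Da.
#' @return Mass shift in Daltons.
#' @export
n15_mass_adjustment <- function(peptide, incorporation, exact = FALSE) {
  if (!is.numeric(incorporation) || length(incorporation) != 1L ||
      is.na(incorporation) || incorporation < 0 || incorporation > 1) {
    stop("'incorporation' must be a single number in [0, 1]")
  }
  n <- peptide_nitrogens(peptide)
  per_n <- if (exact) incorporation * .N15_DELTA else incorporation
  n * per_n
}

# Single-atom distribution of one element at a given 15N fraction, as parallel
# vectors over nominal offsets 0..(n_peaks-1): intensity I and first mass
# moment M (sum of probability * isotopologue mass).
.atom_dist <- function(element, n15_fraction, n_peaks) {
  tab <- .ISOTOPES[[element]]
  ab <- tab$abundance
  if (element == "N") ab <- c(1 - n15_fraction, n15_fraction)
  I <- numeric(n_peaks)
  M <- numeric(n_peaks)
  keep <- tab$offset < n_peaks
  idx <- tab$offset[keep] + 1L
  I[idx] <- ab[keep]
  M[idx] <- ab[keep] * tab$mass[keep]
  list(I = I, M = M)
}

# Convolution of two (intensity, moment) pairs, truncated at n_peaks offsets.
# Truncation is exact for the retained offsets: higher offsets never feed back
# into lower ones.
.conv <- function(a, b) {
  K <- length(a$I)
  I <- numeric(K)
  M <- numeric(K)
  for (k in seq_len(K)) {
    i <- seq_len(k)
    j <- k - i + 1L
    I[k] <- sum(a$I[i] * b$I[j])
    M[k] <- sum(a$M[i] * b$I[j] + a$I[i] * b$M[j])
  }
  list(I = I, M = M)
}

# n-fold convolution power by binary exponentiation.
.conv_pow <- function(d, n) {
  K <- length(d$I)
  acc <- list(I = c(1, numeric(K - 1L)), M = numeric(K))
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .conv(acc, d)
    d <- .conv(d, d)
    n <- n %/% 2L
  }
  acc
}

.envelope_raw <- function(comp, n15_fraction, n_peaks) {
  comp <- .as_composition(comp)
  acc <- list(I = c(1, numeric(n_peaks - 1L)), M = numeric(n_peaks))
  for (el in names(comp)) {
    if (comp[[el]] > 0L) {
      acc <- .conv(acc, .conv_pow(.atom_dist(el, n15_fraction, n_peaks), comp[[el]]))
    }
  }
  acc
}

#' Theoretical isotope intensity distribution
#'
#' Relative intensities of the first `n_peaks` isotopologue peaks of a
#' composition, with the nitrogen heavy-isotope probability set to
#' `n15_fraction`. At the natural 15N abundance (0.003663) this is the
#' natural-abundance pattern; at metabolic-labeling enrichments (e.g. 0.95)
#' the envelope shifts up by roughly one nominal mass per nitrogen atom.
#' Intensities are renormalized to sum to 1 after truncation.
#'
#' @param comp Composition vector or peptide string.
#' @param n15_fraction Probability that any one nitrogen is 15N, in \[0, 1\].
#' @param n_peaks Number of nominal-mass peaks to return (offset 0 upward).
#' @return Numeric vector of `n_peaks` intensities summing to 1.
#' @export
#' @examples
#' isotope_distribution(c(N = 2), n15_fraction = 0.95, n_peaks = 3)
isotope_distribution <- function(comp, n15_fraction = .N15_NATURAL,
                                 n_peaks = 6L) {
  if (!is.numeric(n15_fraction) || n15_fraction < 0 || n15_fraction > 1) {
    stop("'n15_fraction' must be in [0, 1]")
  }
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_peaks) || n_peaks < 1L) stop("'n_peaks' must be >= 1")
  I <- .envelope_raw(comp, n15_fraction, n_peaks)$I
  I / sum(I)
}

#' Theoretical isotope envelope with m/z values
#'
#' Like [isotope_distribution()] but also computes the intensity-weighted
#' exact mass of each nominal peak and converts to m/z using
#' `mz = (M + z * 1.007276) / z`.
#'
#' @inheritParams isotope_distribution
#' @param charge Positive integer charge state.
#' @return An object of class `isotope_envelope`: list with `charge`,
#'   `mz_values`, `intensities` (normalized), and `mean_mass` (intensity-
#'   weighted neutral mass in Da).
#' @export
theoretical_envelope <- function(comp, charge = 2L,
                                 n15_fraction = .N15_NATURAL, n_peaks = 6L) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("'charge' must be a positive integer")
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_peaks) || n_peaks < 1L) stop("'n_peaks' must be >= 1")
  raw <- .envelope_raw(comp, n15_fraction, n_peaks)
  I <- raw$I
  M <- raw$M
  mono <- monoisotopic_mass(comp)
  # Peak mass = moment / intensity; empty peaks fall back to nominal spacing.
  mass_k <- ifelse(I > 0, M / pmax(I, .Machine$double.xmin),
                   mono + (seq_along(I) - 1L) * 1.0033548378)
  total <- sum(I)
  structure(
    list(
      charge = charge,
      mz_values = (mass_k + charge * .PROTON_MASS) / charge,
      intensities = I / total,
      mean_mass = sum(I * mass_k) / total
    ),
    class = "isotope_envelope"
  )
}

#' Intensity-weighted mean neutral mass of an envelope
#' @param envelope An `isotope_envelope`.
#' @return Mass in Daltons.
#' @export
envelope_mean_mass <- function(envelope) {
  if (!inherits(envelope, "isotope_envelope")) stop("not an isotope_envelope")
  envelope$mean_mass
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Classify an observed envelope as natural or 15N-enriched
#'
#' Compares an observed isotope envelope against two theoretical templates for
#' the same composition — natural abundance and labeled at
#' `n15_fraction_labeled` — by cosine similarity of the intensity vectors
#' (truncated to the observed length and renormalized). Natural-template
#' features are the male-derived (unlabeled) candidates used to build
#' inclusion lists; ties go to natural.
#'
#' @param observed An `isotope_envelope` (or list with `intensities`).
#' @param comp Composition vector or peptide string.
#' @param n15_fraction_labeled 15N fraction of the labeled template
#'   (default 0.95).
#' @return List with `call` (`"natural"` or `"enriched"`),
#'   `score_natural`, `score_enriched`.
#' @export
classify_envelope <- function(observed, comp, n15_fraction_labeled = 0.95) {
  obs <- observed$intensities
  if (is.null(obs) || !length(obs)) stop("observed envelope has no intensities")
  n <- length(obs)
  nat <- isotope_distribution(comp, .N15_NATURAL, n)
  lab <- isotope_distribution(comp, n15_fraction_labeled, n)
  if (length(nat) != n || length(lab) != n) {
    stop("template/observed length mismatch after truncation")
  }
  s_nat <- .cosine(obs, nat)
  s_lab <- .cosine(obs, lab)
  list(
    call = if (s_nat >= s_lab) "natural" else "enriched",
    score_natural = s_nat,
    score_enriched = s_lab
  )
}
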