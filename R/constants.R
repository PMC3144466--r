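# Pinned physical constants. The source literature for this kind of analysis
# never restates isotope masses or abundances, so they are fixed here (CODATA /
# IUPAC 1997 values, the ones mass-spec search engines conventionally use) and
# mirrored as a human-readable table in inst/extdata/element_isotopes.tsv.

#' @keywords internal
.PROTON_MASS <- 1.007276466

#' Mass difference between 15N and 14N in Daltons.
#' @keywords internal
.N15_DELTA <- 0.9970349

#' Natural abundance of 15N.
#' @keywords internal
.N15_NATURAL <- 0.003663

# Monoisotopic masses of the light isotope of each element (Da).
.MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.WATER_MASS <- 2 * .MONO_MASS[["H"]] + .MONO_MASS[["O"]]

# Per-element isotope tables: nominal mass offset from the light isotope,
# exact isotopologue mass, natural abundance. Abundances sum to 1 per element.
.ISOTOPES <- list(
  C = data.frame(
    offset = c(0L, 1L),
    mass = c(12.0, 13.0033548378),
    abundance = c(0.9893, 0.0107)
  ),
  H = data.frame(
    offset = c(0L, 1L),
    mass = c(1.0078250319, 2.0141017781),
    abundance = c(0.999885, 0.000115)
  ),
  N = data.frame(
    offset = c(0L, 1L),
    mass = c(14.0030740052, 15.0001088984),
    abundance = c(1 - 0.003663, 0.003663)
  ),
  O = data.frame(
    offset = c(0L, 1L, 2L),
    mass = c(15.9949146221, 16.9991315, 17.9991604),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  S = data.frame(
    offset = c(0L, 1L, 2L, 4L),
    mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
    abundance = c(0.9493, 0.0076, 0.0429, 0.0002)
  )
)

# Residue (not free amino acid) elemental formulas for the 20 standard
# residues: columns C, H, N, O, S. A peptide is the sum of its residues plus
# one water.
.RESIDUE_FORMULAS <- matrix(
  c(
    # C   H   N  O  S
      3,  5,  1, 1, 0,  # A Ala
      6, 12,  4, 1, 0,  # R Arg
      4,  6,  2, 2, 0,  # N Asn
      4,  5,  1, 3, 0,  # D Asp
      3,  5,  1, 1, 1,  # C Cys
      5,  8,  2, 2, 0,  # Q Gln
      5,  7,  1, 3, 0,  # E Glu
      2,  3,  1, 1, 0,  # G Gly
      6,  7,  3, 1, 0,  # H His
      6, 11,  1, 1, 0,  # I Ile
      6, 11,  1, 1, 0,  # L Leu
      6, 12,  2, 1, 0,  # K Lys
      5,  9,  1, 1, 1,  # M Met
      9,  9,  1, 1, 0,  # F Phe
      5,  7,  1, 1, 0,  # P Pro
      3,  5,  1, 2, 0,  # S Ser
      4,  7,  1, 2, 0,  # T Thr
     11, 10,  2, 1, 0,  # W Trp
      9,  9,  1, 2, 0,  # Y Tyr
      5,  9,  1, 1, 0   # V Val
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("C", "H", "N", "O", "S")
  )
)

.AA_ALPHABET <- rownames(.RESIDUE_FORMULAS)

#' Pinned isotope constants
#'
#' Returns the element isotope table used throughout the package: for each of
#' C, H, N, O and S, the nominal mass offset of every stable isotope from the
#' light isotope, its exact mass and its natural abundance. The same values
#' ship as a plain-text table in `inst/extdata/element_isotopes.tsv`.
#'
#' @return A data.frame with columns `element`, `offset`, `mass`, `abundance`.
#' @export
#' @examples
#' isotope_constants()
isotope_constants <- function() {
  do.call(rbind, lapply(names(.ISOTOPES), function(el) {
    cbind(data.frame(element = el, stringsAsFactors = FALSE), .ISOTOPES[[el]])
  }))
}

#' Residue elemental formulas
#'
#' @return A data.frame with one row per standard residue and columns
#'   `residue`, `C`, `H`, `N`, `O`, `S` (counts for the residue, i.e. the
#'   amino acid minus one water).
#' @export
residue_formulas <- function() {
  data.frame(
    residue = rownames(.RESIDUE_FORMULAS),
    .RESIDUE_FORMULAS,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
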