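#' In silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to K or R except when the next
#' residue is proline, and returns all peptides with up to `max_missed`
#' missed cleavages. Peptides are ordered by missed-cleavage count, then
#' N-terminal to C-terminal position.
#'
#' @param sequence Protein sequence (standard one-letter codes).
#' @param max_missed Maximum number of missed cleavages (default 0).
#' @return Character vector of peptides.
#' @export
#' @examples
#' tryptic_digest("AKGR")               # "AK"  "GR"
#' tryptic_digest("AKPGR")              # "AKPGR" (no cleavage before proline)
#' tryptic_digest("AKGR", max_missed = 1)
tryptic_digest <- function(sequence, max_missed = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("'sequence' must be a non-empty character scalar")
  }
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) stop("'max_missed' must be >= 0")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% .AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf(
      "non-standard residue '%s' at position %d", residues[bad[1L]], bad[1L]
    ))
  }
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & residues[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  frags <- substring(sequence, starts, ends)
  out <- character(0)
  for (m in 0:max_missed) {
    k <- length(frags) - m
    if (k < 1L) break
    for (i in seq_len(k)) {
      out <- c(out, paste(frags[i:(i + m)], collapse = ""))
    }
  }
  out
}

# Tryptic peptides inside the simulated detectability window.
.detectable_peptides <- function(sequence, max_missed = 0L,
                                 min_len = 6L, max_len = 30L) {
  p <- tryptic_digest(sequence, max_missed)
  unique(p[nchar(p) >= min_len & nchar(p) <= max_len])
}
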