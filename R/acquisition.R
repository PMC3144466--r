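# Inclusion-list directed acquisition: build m/z x retention-time windows
# around features classified as natural-abundance (male-derived, unlabeled)
# and not yet sampled, decide directed vs data-dependent fragmentation, and
# compare the two acquisition modes on simulated runs.

#' Build an inclusion list
#'
#' One window per feature that is classified as natural-abundance and has not
#' been sampled in a prior replicate: m/z bounds at `center * (1 +/- ppm *
#' 1e-6)` and retention-time bounds at `rt +/- rt_halfwidth` minutes.
#' Windows may overlap and are ordered by (`rt_low`, `mz_low`).
#'
#' @param features data.frame with columns `mz`, `rt`, `is_natural`,
#'   `previously_sampled`.
#' @param ppm m/z half-width in parts per million (default 10).
#' @param rt_halfwidth Retention-time half-width in minutes (default 1.5).
#' @return data.frame `mz_center`, `mz_low`, `mz_high`, `rt_low`, `rt_high`.
#' @export
build_inclusion_list <- function(features, ppm = 10, rt_halfwidth = 1.5) {
  req <- c("mz", "rt", "is_natural", "previously_sampled")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (ppm <= 0 || rt_halfwidth <= 0) stop("tolerances must be positive")
  keep <- features$is_natural & !features$previously_sampled
  f <- features[keep, , drop = FALSE]
  out <- data.frame(
    mz_center = f$mz,
    mz_low = f$mz * (1 - ppm * 1e-6),
    mz_high = f$mz * (1 + ppm * 1e-6),
    rt_low = f$rt - rt_halfwidth,
    rt_high = f$rt + rt_halfwidth
  )
  out <- out[order(out$rt_low, out$mz_low), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an inclusion list as TSV
#'
#' m/z columns are written with five decimal places (sub-ppm at typical
#' precursor masses), retention times with two.
#'
#' @param windows Inclusion list from [build_inclusion_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_inclusion_tsv <- function(windows, path) {
  out <- data.frame(
    mz_center = sprintf("%.5f", windows$mz_center),
    mz_low = sprintf("%.5f", windows$mz_low),
    mz_high = sprintf("%.5f", windows$mz_high),
    rt_low = sprintf("%.2f", windows$rt_low),
    rt_high = sprintf("%.2f", windows$rt_high)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Directed vs data-dependent acquisition decision
#'
#' A precursor is fragmented in directed mode when it falls inside at least
#' one inclusion window (closed intervals on both axes); otherwise the
#' instrument falls back to data-dependent acquisition.
#'
#' @param mz,rt Precursor coordinates.
#' @param windows Inclusion list from [build_inclusion_list()].
#' @return `"directed"` or `"data_dependent"`.
#' @export
acquisition_decision <- function(mz, rt, windows) {
  if (nrow(windows) &&
      any(mz >= windows$mz_low & mz <= windows$mz_high &
          rt >= windows$rt_low & rt <= windows$rt_high)) {
    "directed"
  } else {
    "data_dependent"
  }
}

#' Simulate one acquisition run over a feature table
#'
#' A schematic instrument model: survey scans step through retention time;
#' in each scan the `top_n` most intense co-eluting features are fragmented,
#' except that in directed mode features inside an inclusion window are
#' fragmented first (most intense first), with any remaining capacity filled
#' data-dependently. A feature is fragmented at most once per run (dynamic
#' exclusion).
#'
#' @param features data.frame with columns `feature_id`, `gene_id`, `mz`,
#'   `rt`, `intensity`.
#' @param windows Optional inclusion list; `NULL` means pure data-dependent
#'   acquisition.
#' @param top_n Fragmentation events per scan cycle.
#' @param scan_width Retention-time width of one scan cycle in minutes.
#' @return data.frame of sampled features with a `mode` column.
#' @export
simulate_acquisition_run <- function(features, windows = NULL, top_n = 3L,
                                     scan_width = 0.5) {
  req <- c("feature_id", "gene_id", "mz", "rt", "intensity")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  sampled <- logical(nrow(features))
  out <- list()
  scan_times <- seq(floor(min(features$rt)), ceiling(max(features$rt)),
                    by = scan_width)
  for (t in scan_times) {
    eluting <- which(!sampled & abs(features$rt - t) <= scan_width / 2)
    if (!length(eluting)) next
    chosen <- integer(0)
    if (!is.null(windows) && nrow(windows)) {
      in_win <- eluting[vapply(eluting, function(i) {
        acquisition_decision(features$mz[i], features$rt[i],
                             windows) == "directed"
      }, logical(1))]
      in_win <- in_win[order(-features$intensity[in_win])]
      chosen <- utils::head(in_win, top_n)
    }
    if (length(chosen) < top_n) {
      rest <- setdiff(eluting, chosen)
      rest <- rest[order(-features$intensity[rest])]
      chosen <- c(chosen, utils::head(rest, top_n - length(chosen)))
    }
    sampled[chosen] <- TRUE
    if (length(chosen)) {
      hit <- features[chosen, , drop = FALSE]
      hit$mode <- if (is.null(windows)) "data_dependent" else "directed"
      out[[length(out) + 1L]] <- hit
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- cbind(features[integer(0), , drop = FALSE],
                 mode = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Compare directed and data-dependent acquisition
#'
#' Per-gene spectral-count difference (directed minus data-dependent) on two
#' runs of the same sample, aligned on the union of genes with zero fill.
#'
#' @param directed,dda data.frames with a `gene_id` column, one row per
#'   sampled spectrum (e.g. from [simulate_acquisition_run()]).
#' @return List with `per_gene` (data.frame `gene_id`, `n_directed`,
#'   `n_dda`, `delta`), `median_delta` and `quartiles`.
#' @export
compare_directed_vs_dda <- function(directed, dda) {
  genes <- sort(union(directed$gene_id, dda$gene_id))
  n_dir <- vapply(genes, function(g) sum(directed$gene_id == g), numeric(1))
  n_dda <- vapply(genes, function(g) sum(dda$gene_id == g), numeric(1))
  per_gene <- data.frame(
    gene_id = genes, n_directed = n_dir, n_dda = n_dda,
    delta = n_dir - n_dda, row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    per_gene = per_gene,
    median_delta = stats::median(per_gene$delta),
    quartiles = stats::quantile(per_gene$delta, c(0.25, 0.75), names = FALSE)
  )
}

#' Derive MS1 features from a simulated PSM table
#'
#' Collapses a PSM table to unique peptide features with m/z (at the PSM's
#' charge), a synthetic retention time, summed intensity proxy (spectral
#' count), a natural/enriched flag from the label-mode ground truth, and gene
#' assignment by peptide mapping.
#'
#' @param psms PSM data.frame (one sample).
#' @param mapping Mapping from [map_peptides()].
#' @param seed Seed for retention times.
#' @return Feature data.frame suitable for [build_inclusion_list()] and
#'   [simulate_acquisition_run()].
#' @export
psm_features <- function(psms, mapping, seed = 1L) {
  glist <- .mapping_list(mapping)
  .with_seed(seed, {
    peps <- unique(psms$peptide)
    rows <- lapply(seq_along(peps), function(i) {
      pep <- peps[i]
      sub <- psms[psms$peptide == pep, , drop = FALSE]
      z <- sub$charge[1L]
      genes <- glist[[pep]]
      data.frame(
        feature_id = sprintf("feat%05d", i),
        gene_id = if (length(genes)) genes[1L] else NA_character_,
        peptide = pep,
        mz = (sub$observed_mass[1L] + z * .PROTON_MASS) / z,
        rt = stats::runif(1L, 5, 115),
        intensity = nrow(sub),
        is_natural = sub$label_mode_truth[1L] == "unlabeled",
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
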