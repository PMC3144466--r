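# Synthetic-data generator: proteome fixtures, experiment designs and PSM
# tables with the statistical structure of a 15N-labeling ejaculate
# experiment — female proteins metabolically labeled at ~95% with rare
# unlabeled leakage, a small set of copulatory-plug proteins carrying a large
# share of male spectra, paralog families producing multi-mapping peptides,
# and decoy/false matches for FDR machinery.

# Run code with a private RNG state so generators are deterministic per seed
# without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_protein <- function(len) {
  # K+R at ~11% gives mean tryptic peptide length ~9, a realistic digest.
  freq <- c(
    A = 8.3, R = 5.5, N = 4.0, D = 5.5, C = 1.4, Q = 3.9, E = 6.8, G = 7.1,
    H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9, P = 4.7, S = 6.6,
    T = 5.4, W = 1.1, Y = 2.9, V = 6.9
  )
  paste(sample(names(freq), len, replace = TRUE, prob = freq), collapse = "")
}

#' Generate a synthetic proteome fixture
#'
#' Builds a proteome of male-derived (seminal and copulatory-plug), female-
#' derived and optional contaminant proteins. A configurable fraction of genes
#' is grouped into paralog families that share at least one identical
#' detectable tryptic peptide (length >= 6), to exercise multi-mapping;
#' outside families no detectable tryptic peptide occurs in two genes. With
#' the default `n_plug = 7` the plug genes are named after the seminal
#' vesicle secretions and transglutaminase whose cross-linked products
#' dominate plug samples.
#'
#' @param n_male,n_female,n_plug Gene counts (`n_plug <= n_male`).
#' @param length_range Integer range of protein lengths in residues.
#' @param family_fraction Fraction of genes placed into paralog families,
#'   in \[0, 1).
#' @param seed Integer seed; output is deterministic per seed.
#' @param n_contaminant Number of contaminant proteins (default 0).
#' @return An object of class `proteome_fixture`: list with `proteins`
#'   (data.frame `gene_id`, `origin`, `sequence`) and `family_map` (named
#'   character vector gene_id -> family id; singleton genes get their own id).
#' @export
generate_proteome <- function(n_male = 20L, n_female = 30L, n_plug = 7L,
                              length_range = c(80L, 400L),
                              family_fraction = 0.2, seed = 1L,
                              n_contaminant = 0L) {
  n_male <- as.integer(n_male); n_female <- as.integer(n_female)
  n_plug <- as.integer(n_plug); n_contaminant <- as.integer(n_contaminant)
  if (n_male < 1L || n_female < 1L || n_plug < 1L) stop("counts must be > 0")
  if (n_plug > n_male) stop("'n_plug' must not exceed 'n_male'")
  if (n_contaminant < 0L) stop("'n_contaminant' must be >= 0")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] < 20L || length_range[1L] > length_range[2L]) {
    stop("'length_range' must be an increasing pair of lengths >= 20")
  }
  if (!is.numeric(family_fraction) || family_fraction < 0 ||
      family_fraction >= 1) {
    stop("'family_fraction' must be in [0, 1)")
  }

  plug_names <- if (n_plug == 7L) {
    c("Svs1", "Svs2", "Svs3a", "Svs3b", "Svs4", "Svs5", "Tgm4")
  } else {
    sprintf("plug%02d", seq_len(n_plug))
  }
  gene_id <- c(
    plug_names,
    sprintf("male%03d", seq_len(n_male - n_plug)),
    sprintf("fem%03d", seq_len(n_female)),
    if (n_contaminant > 0L) sprintf("cont%02d", seq_len(n_contaminant))
  )
  origin <- c(
    rep("male_plug", n_plug),
    rep("male_seminal", n_male - n_plug),
    rep("female", n_female),
    rep("contaminant", n_contaminant)
  )
  n_genes <- length(gene_id)

  .with_seed(seed, {
    seen <- new.env(parent = emptyenv())  # detectable peptide -> TRUE
    register <- function(peps) for (p in peps) assign(p, TRUE, envir = seen)
    fresh_sequence <- function(len, need_peps = TRUE) {
      for (try in 1:200) {
        s <- .random_protein(len)
        peps <- .detectable_peptides(s)
        if (need_peps && length(peps) < 2L) next
        if (!any(vapply(peps, exists, logical(1), envir = seen))) {
          register(peps)
          return(s)
        }
      }
      stop("failed to generate a peptide-disjoint sequence")
    }

    lens <- sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE)
    sequences <- character(n_genes)
    family_map <- paste0("F_", gene_id)
    names(family_map) <- gene_id

    n_family_genes <- floor(family_fraction * n_genes)
    fam_members <- if (n_family_genes >= 2L) {
      sample(seq_len(n_genes), n_family_genes)
    } else integer(0)
    # Partition family members into families of size >= 2, never mixing
    # male- and female-origin genes in one family (paralog families are
    # origin-coherent; a peptide shared across origins would make the
    # labeling ground truth ill-defined).
    families <- list()
    is_male_origin <- origin %in% c("male_plug", "male_seminal")
    for (members in list(fam_members[is_male_origin[fam_members]],
                         fam_members[!is_male_origin[fam_members]])) {
      i <- 1L
      while (length(members) - i + 1L >= 2L) {
        size <- min(sample(2:3, 1L), length(members) - i + 1L)
        if (length(members) - (i + size - 1L) == 1L) size <- size + 1L
        families[[length(families) + 1L]] <- members[i:(i + size - 1L)]
        i <- i + size
      }
    }
    in_family <- unlist(families)

    for (g in setdiff(seq_len(n_genes), in_family)) {
      sequences[g] <- fresh_sequence(lens[g])
    }
    fam_id <- 0L
    for (fam in families) {
      fam_id <- fam_id + 1L
      head_g <- fam[1L]
      sequences[head_g] <- fresh_sequence(lens[head_g])
      shared_pool <- .detectable_peptides(sequences[head_g])
      # An internal tryptic peptide ends in K/R; prefer those so the shared
      # peptide survives digestion when spliced into relatives.
      ends_kr <- grepl("[KR]$", shared_pool)
      shared <- sample(shared_pool[if (any(ends_kr)) ends_kr else TRUE], 1L)
      for (g in fam[-1L]) {
        for (try in 1:200) {
          base <- .random_protein(max(lens[g] - nchar(shared), 30L))
          res <- strsplit(base, "", fixed = TRUE)[[1L]]
          sites <- which(res %in% c("K", "R"))
          sites <- sites[sites < length(res) & res[sites + 1L] != "P"]
          if (!length(sites)) next
          at <- sample(sites, 1L)
          cand <- paste0(
            substr(base, 1L, at), shared, substr(base, at + 1L, nchar(base))
          )
          peps <- setdiff(.detectable_peptides(cand), shared)
          if (!any(vapply(peps, exists, logical(1), envir = seen))) {
            register(peps)
            sequences[g] <- cand
            break
          }
        }
        if (!nzchar(sequences[g])) stop("failed to build family member")
      }
      family_map[fam] <- sprintf("FAM%02d", fam_id)
    }

    structure(
      list(
        proteins = data.frame(
          gene_id = gene_id, origin = origin, sequence = sequences,
          stringsAsFactors = FALSE
        ),
        family_map = family_map
      ),
      class = "proteome_fixture"
    )
  })
}

#' Write / read a proteome fixture as FASTA
#'
#' Headers have the form `gene_id|origin|family`.
#'
#' @param fixture A `proteome_fixture`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `proteome_fixture` (reader).
#' @export
write_proteome_fasta <- function(fixture, path) {
  stopifnot(inherits(fixture, "proteome_fixture"))
  p <- fixture$proteins
  seqs <- Biostrings::AAStringSet(p$sequence)
  names(seqs) <- paste(p$gene_id, p$origin, fixture$family_map[p$gene_id],
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene_id <- vapply(parts, `[`, character(1), 1L)
  origin <- vapply(parts, `[`, character(1), 2L)
  family <- vapply(parts, `[`, character(1), 3L)
  names(family) <- gene_id
  structure(
    list(
      proteins = data.frame(
        gene_id = gene_id, origin = origin,
        sequence = as.character(seqs), stringsAsFactors = FALSE,
        row.names = NULL
      ),
      family_map = family
    ),
    class = "proteome_fixture"
  )
}

#' Default experiment design
#'
#' The study layout this generator emulates: two copulatory-plug samples run
#' in seven technical replicates each, two uterine-fluid samples in five
#' replicates each, and one unmated-control sample, with female proteins
#' labeled at 95% 15N incorporation.
#'
#' @param enrichment 15N incorporation of female-derived proteins.
#' @param leakage_rate Probability that a female-origin PSM is unlabeled
#'   (incomplete label incorporation / slow protein turnover). Kept rare by
#'   default: at typical per-gene spectral depths a rate of 0.002 leaks an
#'   unlabeled peptide or two from only the most abundant female proteins,
#'   the pattern such experiments actually show.
#' @param induced_fraction Fraction of female genes that are mating-induced,
#'   i.e. expressed in mated samples but absent from the unmated control.
#' @param meanlog,sdlog Log-normal location/scale of per-gene expected
#'   experiment-wide spectra.
#' @param plug_share Expected fraction of male spectra carried by the plug
#'   genes; the plug multiplier is calibrated to this target.
#' @param decoy_rate Expected decoy (and false-target) PSMs as a fraction of
#'   true PSMs per table.
#' @param score_true_mean,score_null_mean,score_sd Normal score model for
#'   correct matches and for decoy/false matches.
#' @param seed Integer root seed for [simulate_experiment()].
#' @return An object of class `experiment_design`.
#' @export
default_design <- function(enrichment = 0.95, leakage_rate = 0.002,
                           induced_fraction = 0.4,
                           meanlog = log(120), sdlog = 1.3,
                           plug_share = 0.37, decoy_rate = 0.1,
                           score_true_mean = 4, score_null_mean = 2,
                           score_sd = 1, seed = 1L) {
  for (f in c(enrichment, leakage_rate, induced_fraction, plug_share,
              decoy_rate)) {
    if (!is.numeric(f) || f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  structure(
    list(
      samples = data.frame(
        sample_id = c("plug1", "plug2", "uterine1", "uterine2", "unmated1"),
        kind = c("plug", "plug", "uterine", "uterine", "unmated_control"),
        n_replicates = c(7L, 7L, 5L, 5L, 1L),
        stringsAsFactors = FALSE
      ),
      enrichment = enrichment,
      leakage_rate = leakage_rate,
      induced_fraction = induced_fraction,
      abundance_model = list(meanlog = meanlog, sdlog = sdlog,
                             plug_share = plug_share),
      decoy_rate = decoy_rate,
      score_model = list(true_mean = score_true_mean,
                         null_mean = score_null_mean, sd = score_sd),
      seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

# Expected per-gene spectra with the plug multiplier calibrated so that plug
# genes carry `plug_share` of the expected male total.
.gene_lambdas <- function(fixture, design) {
  p <- fixture$proteins
  am <- design$abundance_model
  lambda <- stats::rlnorm(nrow(p), meanlog = am$meanlog, sdlog = am$sdlog)
  names(lambda) <- p$gene_id
  is_plug <- p$origin == "male_plug"
  is_male <- p$origin %in% c("male_plug", "male_seminal")
  if (any(is_plug) && any(is_male & !is_plug) && am$plug_share > 0 &&
      am$plug_share < 1) {
    mult <- am$plug_share / (1 - am$plug_share) *
      sum(lambda[is_male & !is_plug]) / sum(lambda[is_plug])
    lambda[is_plug] <- lambda[is_plug] * mult
  }
  lambda
}

#' Simulate a labeled-ejaculate experiment
#'
#' Draws PSM tables, one per sample x technical replicate, from a proteome
#' fixture under an experiment design. Male-derived spectra are unlabeled;
#' female-origin spectra are 15N-labeled with probability
#' `1 - leakage_rate` (labeled observed masses carry the exact per-nitrogen
#' shift at the design's enrichment). Plug genes receive their calibrated
#' abundance multiplier in plug and uterine samples; the unmated control
#' contains only female-origin (and contaminant) spectra. Decoy PSMs and
#' score-matched false target PSMs are injected at `decoy_rate` so that
#' target-decoy FDR behaves as in a real search.
#'
#' @param fixture A `proteome_fixture`.
#' @param design An `experiment_design`.
#' @param seed Optional override of `design$seed`.
#' @return Named list of data.frames (one per `sample.replicate`) with
#'   columns `spectrum_id`, `sample_id`, `replicate`, `peptide`, `charge`,
#'   `observed_mass`, `score`, `is_decoy`, `label_mode_truth`, `match_truth`.
#'   The attribute `induced_female_truth` records which female genes were
#'   simulated as mating-induced (absent from the unmated control).
#' @export
simulate_experiment <- function(fixture, design = default_design(),
                                seed = NULL) {
  stopifnot(inherits(fixture, "proteome_fixture"),
            inherits(design, "experiment_design"))
  if (nrow(fixture$proteins) == 0L) stop("fixture is empty")
  seed <- if (is.null(seed)) design$seed else as.integer(seed)

  p <- fixture$proteins
  peptides_by_gene <- lapply(p$sequence, .detectable_peptides)
  names(peptides_by_gene) <- p$gene_id
  has_peps <- lengths(peptides_by_gene) > 0L
  pep_pool <- unique(unlist(peptides_by_gene))
  pep_mass <- vapply(pep_pool, function(x) monoisotopic_mass(x), numeric(1))
  pep_nN <- vapply(pep_pool, peptide_nitrogens, integer(1))

  sm <- design$score_model

  .with_seed(seed, {
    lambda <- .gene_lambdas(fixture, design)
    lambda[!has_peps] <- 0
    induced_fraction <- if (is.null(design$induced_fraction)) 0
      else design$induced_fraction
    is_induced <- p$origin == "female" &
      stats::runif(nrow(p)) < induced_fraction

    tables <- list()
    for (si in seq_len(nrow(design$samples))) {
      sample_id <- design$samples$sample_id[si]
      kind <- design$samples$kind[si]
      n_rep <- design$samples$n_replicates[si]

      present <- switch(kind,
        plug = ,
        uterine = rep(TRUE, nrow(p)),
        unmated_control =
          (p$origin == "female" & !is_induced) | p$origin == "contaminant"
      )
      # Split each gene's experiment-wide expectation across the samples in
      # which it occurs.
      n_samples_present <- vapply(seq_len(nrow(p)), function(g) {
        sum(vapply(design$samples$kind, function(k) {
          k != "unmated_control" ||
            ((p$origin[g] == "female" && !is_induced[g]) ||
               p$origin[g] == "contaminant")
        }, logical(1)))
      }, numeric(1))
      lam_s <- ifelse(present, lambda / pmax(n_samples_present, 1L), 0)

      totals <- stats::rpois(nrow(p), lam_s)
      rows <- vector("list", sum(totals > 0) + 2L)
      ri <- 0L
      for (g in which(totals > 0L)) {
        n_g <- totals[g]
        peps <- peptides_by_gene[[g]]
        pep <- sample(peps, n_g, replace = TRUE)
        rep_of <- sample.int(n_rep, n_g, replace = TRUE)
        labeled <- if (p$origin[g] == "female") {
          stats::runif(n_g) > design$leakage_rate
        } else rep(FALSE, n_g)
        nN <- pep_nN[pep]
        mass <- pep_mass[pep] +
          ifelse(labeled, nN * design$enrichment * .N15_DELTA, 0)
        mass <- mass * (1 + stats::rnorm(n_g, 0, 3e-6))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = sample_id, replicate = rep_of, peptide = pep,
          charge = sample(2:3, n_g, replace = TRUE),
          observed_mass = mass,
          score = stats::rnorm(n_g, sm$true_mean, sm$sd),
          is_decoy = FALSE,
          label_mode_truth = ifelse(labeled, "labeled", "unlabeled"),
          match_truth = "true", stringsAsFactors = FALSE
        )
      }
      n_true <- sum(totals)
      # Decoy matches: random-sequence peptides scored from the null.
      n_decoy <- stats::rpois(1L, design$decoy_rate * n_true)
      if (n_decoy > 0L) {
        dec_pep <- vapply(seq_len(n_decoy), function(i) {
          paste(c(sample(setdiff(.AA_ALPHABET, c("K", "R", "P")),
                         sample(7:15, 1L), replace = TRUE), "R"),
                collapse = "")
        }, character(1))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = sample_id,
          replicate = sample.int(n_rep, n_decoy, replace = TRUE),
          peptide = dec_pep,
          charge = sample(2:3, n_decoy, replace = TRUE),
          observed_mass = vapply(dec_pep, function(x) monoisotopic_mass(x),
                                 numeric(1)),
          score = stats::rnorm(n_decoy, sm$null_mean, sm$sd),
          is_decoy = TRUE, label_mode_truth = "unlabeled",
          match_truth = "decoy", stringsAsFactors = FALSE
        )
      }
      # False target matches, same score null as decoys — the assumption
      # target-decoy FDR rests on. A genome-scale search spreads false
      # matches over the whole database, of which the fixture is a small
      # part: most false matches therefore hit peptides of "other" genome
      # proteins (random sequences that map to no fixture gene), and only a
      # small fraction collide with fixture peptides.
      n_false <- stats::rpois(1L, design$decoy_rate * n_true)
      if (n_false > 0L && length(pep_pool)) {
        hit_fixture <- stats::runif(n_false) < 0.1
        fp <- character(n_false)
        fp[hit_fixture] <- sample(pep_pool, sum(hit_fixture), replace = TRUE)
        fp[!hit_fixture] <- vapply(seq_len(sum(!hit_fixture)), function(i) {
          paste(c(sample(setdiff(.AA_ALPHABET, c("K", "R", "P")),
                         sample(7:15, 1L), replace = TRUE), "K"),
                collapse = "")
        }, character(1))
        fmass <- ifelse(hit_fixture, pep_mass[fp],
                        vapply(fp, function(x) monoisotopic_mass(x),
                               numeric(1), USE.NAMES = FALSE))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = sample_id,
          replicate = sample.int(n_rep, n_false, replace = TRUE),
          peptide = fp,
          charge = sample(2:3, n_false, replace = TRUE),
          observed_mass = unname(fmass) * (1 + stats::rnorm(n_false, 0, 3e-6)),
          score = stats::rnorm(n_false, sm$null_mean, sm$sd),
          is_decoy = FALSE, label_mode_truth = "unlabeled",
          match_truth = "random", stringsAsFactors = FALSE
        )
      }
      tab <- do.call(rbind, rows[seq_len(ri)])
      if (is.null(tab)) {
        tab <- data.frame(
          sample_id = character(0), replicate = integer(0),
          peptide = character(0), charge = integer(0),
          observed_mass = numeric(0), score = numeric(0),
          is_decoy = logical(0), label_mode_truth = character(0),
          match_truth = character(0), stringsAsFactors = FALSE
        )
      }
      for (r in seq_len(n_rep)) {
        sub <- tab[tab$replicate == r, , drop = FALSE]
        sub <- sub[order(sub$peptide, sub$score), , drop = FALSE]
        if (nrow(sub)) {
          sub$spectrum_id <- sprintf("%s_r%d_s%05d", sample_id, r,
                                     seq_len(nrow(sub)))
        } else sub$spectrum_id <- character(0)
        sub <- sub[, c("spectrum_id", "sample_id", "replicate", "peptide",
                       "charge", "observed_mass", "score", "is_decoy",
                       "label_mode_truth", "match_truth")]
        rownames(sub) <- NULL
        tables[[paste0(sample_id, ".", r)]] <- sub
      }
    }
    attr(tables, "induced_female_truth") <- p$gene_id[is_induced]
    tables
  })
}

#' Combine per-replicate PSM tables into one data.frame
#' @param tables List of PSM data.frames from [simulate_experiment()].
#' @return Single data.frame.
#' @export
psm_bind <- function(tables) {
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Write / read PSM tables as TSV
#' @param psms A PSM data.frame (e.g. from [psm_bind()]).
#' @param path File path.
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate synthetic evolutionary-rate and site-model tables
#'
#' Produces a pairwise ortholog table (aligned codons, dN, dS), a site-model
#' fit table (M7/M8/M8a log-likelihoods, the M8 extra omega class and its
#' proportion, FEL positively selected site count, and the max pairwise
#' dS / genome-median ratio), and truth labels. Genes marked selected draw
#' M8-vs-M7 and M8-vs-M8a likelihood gaps from noncentral chi-square
#' distributions scaled by `effect` and receive an extra omega class above
#' 1.1 with class proportion >= 1%; null genes draw the gaps from the central
#' chi-square, so the five-criterion verdict's type-I rate is governed by the
#' product of the two LRT alphas. A fraction of records violate each
#' quality-control rule, flagged in the truth table.
#'
#' @param n_genes Number of genes.
#' @param fraction_selected Fraction of genes simulated under recurrent
#'   positive selection.
#' @param effect Selection effect size (shifts the extra omega class and the
#'   likelihood-gap noncentrality).
#' @param seed Integer seed.
#' @param qc_violation_rate Fraction of genes violating each QC rule.
#' @return List with `orthologs`, `fits`, `truth` data.frames.
#' @export
generate_evolution_table <- function(n_genes, fraction_selected = 0.1,
                                     effect = 2, seed = 1L,
                                     qc_violation_rate = 0.05) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0L) stop("'n_genes' must be >= 0")
  if (fraction_selected < 0 || fraction_selected > 1) {
    stop("'fraction_selected' must be in [0, 1]")
  }
  if (n_genes == 0L) {
    empty_orth <- data.frame(
      gene_id = character(0), aligned_codons = integer(0),
      dN = numeric(0), dS = numeric(0)
    )
    empty_fit <- data.frame(
      gene_id = character(0), lnL_M7 = numeric(0), lnL_M8 = numeric(0),
      lnL_M8a = numeric(0), omega_extra = numeric(0), prop_extra = numeric(0),
      fel_sites = integer(0), pairwise_dS_max_ratio = numeric(0)
    )
    empty_truth <- data.frame(
      gene_id = character(0), selected = logical(0),
      qc_violation = character(0)
    )
    return(list(orthologs = empty_orth, fits = empty_fit, truth = empty_truth))
  }
  .with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    selected <- stats::runif(n_genes) < fraction_selected

    # Pairwise mouse-rat-style rates: dS around a genome median ~0.13..0.17,
    # omega lognormal around 0.13.
    dS <- stats::rgamma(n_genes, shape = 4, rate = 25)
    omega <- stats::rlnorm(n_genes, log(0.13), 0.7)
    omega[selected] <- omega[selected] * (1 + effect / 2)
    dN <- omega * dS
    codons <- sample(100:900, n_genes, replace = TRUE)

    qc_violation <- rep("", n_genes)
    pick <- function(rate, avoid) {
      cand <- which(qc_violation == "" & !avoid)
      cand[stats::runif(length(cand)) < rate]
    }
    v <- pick(qc_violation_rate, rep(FALSE, n_genes))
    codons[v] <- sample(30:99, length(v), replace = TRUE)
    qc_violation[v] <- "codons"
    v <- pick(qc_violation_rate, rep(FALSE, n_genes))
    dN[v] <- 1 + stats::rexp(length(v), 2)
    qc_violation[v] <- "dN"
    v <- pick(qc_violation_rate, rep(FALSE, n_genes))
    dS[v] <- 0.381 + stats::rexp(length(v), 5)
    qc_violation[v] <- "dS"

    # Site-model fits. 2dL gaps: noncentral chi-square for selected genes
    # (noncentrality grows with effect, keeping them above the critical
    # values), central chi-square for null genes.
    two_dL1 <- ifelse(selected,
                      stats::rchisq(n_genes, df = 2, ncp = 12 * effect),
                      stats::rchisq(n_genes, df = 2))
    two_dL2 <- ifelse(selected,
                      stats::rchisq(n_genes, df = 1, ncp = 8 * effect),
                      stats::rchisq(n_genes, df = 1))
    lnL_M7 <- -5000 + stats::rnorm(n_genes, 0, 50)
    lnL_M8 <- lnL_M7 + two_dL1 / 2
    lnL_M8a <- lnL_M8 - two_dL2 / 2
    omega_extra <- ifelse(selected,
                          1.1 + effect * stats::runif(n_genes, 0.5, 1.5),
                          stats::runif(n_genes, 0.3, 1.3))
    prop_extra <- ifelse(selected,
                         stats::runif(n_genes, 0.01, 0.10),
                         stats::runif(n_genes, 0, 0.05))
    fel_sites <- ifelse(selected,
                        1L + stats::rpois(n_genes, 2),
                        stats::rpois(n_genes, 0.3))
    ratio <- stats::runif(n_genes, 0.3, 1.9)
    v <- pick(qc_violation_rate, rep(FALSE, n_genes))
    ratio[v] <- 2 + stats::rexp(length(v), 2)
    qc_violation[v] <- ifelse(qc_violation[v] == "", "pairwise_dS",
                              qc_violation[v])

    list(
      orthologs = data.frame(
        gene_id = gene_id, aligned_codons = codons, dN = dN, dS = dS,
        stringsAsFactors = FALSE
      ),
      fits = data.frame(
        gene_id = gene_id, lnL_M7 = lnL_M7, lnL_M8 = lnL_M8,
        lnL_M8a = lnL_M8a, omega_extra = omega_extra,
        prop_extra = prop_extra, fel_sites = as.integer(fel_sites),
        pairwise_dS_max_ratio = ratio, stringsAsFactors = FALSE
      ),
      truth = data.frame(
        gene_id = gene_id, selected = selected, qc_violation = qc_violation,
        stringsAsFactors = FALSE
      )
    )
  })
}
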