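# seminalMS

Identification, quantification and evolutionary analysis of ejaculated
proteins from ¹⁵N-labeled reproductive-tract proteomics.

## The problem

Directly cataloguing the proteins a male transfers to a female at mating is
hard because, once inside the female reproductive tract, male and female
proteins are mixed. One powerful design solves this with stable-isotope
metabolic labeling: raise the female on a ¹⁵N diet so that *her* proteins
are isotopically heavy, mate her to an unlabeled male, and recover proteins
from the tract. Peptides with a natural isotope distribution must then be
male-derived (the ejaculate); ¹⁵N-enriched peptides are female-derived.

`seminalMS` implements the complete computational workflow for this design,
for proteomics researchers and evolutionary biologists who want to analyze
— or simulate and power-test — such experiments:

* **Synthetic data**: proteome fixtures with paralog families, and PSM
  tables with the labeling structure of the design (2 copulatory plugs × 7
  technical replicates, 2 uterine fluids × 5 replicates, 1 unmated control;
  95% ¹⁵N incorporation with rare unlabeled leakage; 7 plug proteins
  carrying ~37% of male spectra; injected decoy and false matches).
* **Isotope chemistry**: elemental compositions, monoisotopic masses, the
  ¹⁵N mass adjustment (0.95 Da × nitrogen count, or the physically exact
  shift), theoretical isotope envelopes at arbitrary ¹⁵N enrichment, and
  natural-vs-enriched envelope classification.
* **Identification**: shuffled-decoy databases, per-spectrum target–decoy
  FDR at 0.01, labeled-mode mass matching, peptide-to-gene mapping,
  two-peptide/one-unique protein inference with an ambiguous-gene report,
  fractional spectral counting, and the three-criteria filter for
  mating-induced female proteins.
* **Quantification**: NSAF — for gene *g*,
  `NSAF_g = (count_g / length_g) / Σ_j (count_j / length_j)`,
  with median-transcript-length handling, replicate discovery curves, and
  arcsine-square-root abundance comparisons.
* **Enrichment**: term-for-term hypergeometric tests with Bonferroni
  correction.
* **Evolution**: Nei–Gojobori dN/dS with Jukes–Cantor correction, the
  printed quality-control boundaries (≥ 100 codons, dN ≤ 1, dS < 0.381,
  ≤ 2× genome-median pairwise dS), likelihood-ratio tests on M7/M8/M8a
  site-model fits, and the five-criterion verdict for recurrent positive
  selection, plus Wilcoxon rank-sum and Fisher's exact comparisons.
* **Acquisition**: inclusion lists (m/z ± 10 ppm × rt ± 1.5 min) over
  unlabeled-envelope features and a directed-vs-data-dependent comparison.

## Worked example

Simulate the default experiment, identify male-derived genes at 1%
per-spectrum FDR, and quantify them by NSAF:

```r
library(seminalMS)

fx   <- generate_proteome(seed = 1)                  # 20 male (7 plug) + 30 female genes
tabs <- simulate_experiment(fx, default_design(), seed = 7)
psms <- psm_bind(tabs)                               # 29,494 PSMs in 25 tables

flt  <- filter_psms_fdr(psms, fdr = 0.01)
flt$threshold                                        # 3.47 (est. FDR 0.010)

main <- subset(flt$accepted, sample_id != "unmated1" &
                             label_mode_truth == "unlabeled")
mp   <- map_peptides(unique(main$peptide), fx, min_len = 6)
inf  <- infer_genes(main, mp)                        # 24 genes identified, 0 ambiguous

lens <- setNames(nchar(fx$proteins$sequence), fx$proteins$gene_id)
cts  <- fractional_counts(main, mp)[inf$identified$gene_id]
head(nsaf(cts, lens))
#>   gene_id spectral_count length    nsaf rank
#> 1 male005           2884    116 0.34845    1
#> 2    Svs1           3833    246 0.21837    2
#> 3 male003           1409    158 0.12498    3
#> 4 male006           1566    184 0.11928    4
#> 5 male008           1011    244 0.05807    5
#> 6    Tgm4            555    164 0.04743    6
```

NSAF values sum to exactly 1 over the identified set; short abundant
proteins (here `male005`) outrank longer ones with more raw spectra, which
is the point of the length normalization. The plug proteins (`Svs*`,
`Tgm4`) sit near the top, as they do in real plug samples.

Enrichment and selection statistics work directly from printed counts:

```r
hypergeometric_tail(N = 14720, K = 57, n = 68, k = 5)
#> [1] 6.298958e-06    # antioxidant activity, well below 0.01

selection_verdict(data.frame(
  gene_id = "lactotransferrin", lnL_M7 = -5000,
  lnL_M8 = -5000 + 29.8/2, lnL_M8a = -5000 + 29.8/2 - 22.9/2,
  omega_extra = 3.8, prop_extra = 0.049, fel_sites = 2L))
#>            gene_id   c1   c2   c3   c4   c5 selected
#> 1 lactotransferrin TRUE TRUE TRUE TRUE TRUE     TRUE
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages (simulate →
identify → quantify → enrich → evolve) into one reproducible report bundle,
and `verify_targets()` recomputes every printed-input quantity with its
bound and pass/fail status.

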