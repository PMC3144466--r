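---
title: "Methods: identifying and analyzing ejaculated proteins with seminalMS"
author: "seminalMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and analyzing ejaculated proteins with seminalMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seminalMS)
```

## The experimental design this package models

When a female animal is raised on a ¹⁵N diet, essentially all of her
proteins become isotopically heavy. Proteins recovered from her reproductive
tract after mating then separate cleanly by mass: unlabeled (natural
isotope abundance) peptides must come from the male ejaculate, while
¹⁵N-enriched peptides are female-derived. `seminalMS` implements the full
computational side of such an experiment:

1. **Simulation** of peptide-spectrum matches (PSMs) with the labeling
   structure of the design (`generate_proteome()`, `simulate_experiment()`).
2. **Identification**: target–decoy FDR filtering, peptide-to-gene mapping,
   two-peptide protein inference, and the three-criteria filter for
   mating-induced female proteins.
3. **Quantification** by normalized spectral abundance factors (NSAF).
4. **Functional enrichment** by term-for-term hypergeometric tests with
   Bonferroni correction.
5. **Evolutionary analysis**: dN/dS quality control and a five-criterion
   test for recurrent positive selection from M7/M8/M8a site-model fits.
6. **Directed acquisition**: inclusion lists over unlabeled-envelope
   features and a schematic directed-vs-data-dependent comparison.

Because raw mass-spectrometry data for this kind of study are rarely
deposited, the synthetic-data module is a first-class, tested component: it
defines the statistical conditions under which every downstream stage is
validated.

## The synthetic experiment

### Design defaults

`default_design()` fixes the layout the package emulates: two copulatory
plug samples run in seven technical replicates each, two uterine-fluid
samples in five replicates each, and one unmated control — 25 PSM tables in
total — with female proteins labeled at 95% ¹⁵N incorporation. The default
proteome carries 20 male genes (7 of them copulatory-plug genes, named after
the seminal vesicle secretions and the transglutaminase that cross-links
them), 30 female genes, and optional contaminants.

Parameters that matter, with defaults and rationale:

* **`enrichment = 0.95`** — the ¹⁵N incorporation of female proteins.
  Metabolic labeling never reaches 100%; 95% is the level such diets
  typically achieve and the level the labeled search mode assumes.
* **`leakage_rate = 0.002`** — the probability that a female-origin PSM is
  observed unlabeled (slow-turnover proteins retain light nitrogen). At the
  simulated spectral depths this leaks an unlabeled peptide or two from only
  the most abundant female proteins, so a handful of female genes can be
  misidentified as male — the artifact such experiments actually show, and
  the reason the unmated control exists.
* **`induced_fraction = 0.4`** — the fraction of female genes expressed only
  after mating and therefore absent from the unmated control. Without this
  structure the control would contain every female protein and criterion
  (ii) of the induced-protein filter could never pass.
* **Abundance model** — per-gene expected experiment-wide spectra are
  log-normal (`meanlog = log(120)`, `sdlog = 1.3`), reproducing the
  "few genes, many spectra" skew of ejaculate proteomes. Plug genes receive
  a multiplier calibrated after the draw so that they carry an expected
  **37%** (`plug_share`) of male spectra, the dominance the plug proteins
  show in real samples.
* **`decoy_rate = 0.1`** — decoy PSMs *and* an equal expected number of
  false target matches are injected with scores from a shared null
  (normal, mean 2, sd 1, vs mean 4 for true matches). Drawing both from the
  same null is precisely the assumption target–decoy FDR estimation rests
  on, which makes the FDR machinery analytically testable.
* **Replicates** — each sample's spectra are assigned to technical
  replicates uniformly at random (binomial thinning), so
  discovery curves across replicates are emergent rather than hard-coded:
  abundant genes appear in replicate 1, faint ones trickle in later.

### What the generator does and does not emulate

Simulation happens at the PSM level: no chromatograms, no peak shapes, no
charge-state deconvolution. Retention times (for the acquisition module) are
uniform, not hydrophobicity-based. Score distributions are Gaussian, a
modeling convenience — real search-engine scores are neither Gaussian nor
homoscedastic, but only their rank behavior matters for the FDR machinery
exercised here. Passing tests therefore validate the *logic* of the
pipeline (thresholding, mapping, inference, normalization, the statistics),
not the behavior of any particular search engine on real spectra.

Two scale artifacts deserve note. First, the fixture holds ~50 genes while
a real search database holds >10⁴; false matches in a real search spread
over the whole database and touch any one interesting gene negligibly. The
generator therefore lets only 10% of false target matches collide with
fixture peptides — the rest represent matches to the remainder of the
genome and map to no fixture gene. Second, tryptic peptides of length
one to five are so short that random proteins share them with probability
near one; uniqueness guarantees (and the `family_fraction = 0` disjointness
property) are defined over the *detectable* window of 6–30 residues, the
window from which the generator samples observable peptides.

## Isotope arithmetic

Peptide elemental compositions use the standard residue formula table plus
one water; monoisotopic masses use pinned light-isotope masses (¹²C, ¹H,
¹⁴N, ¹⁶O, ³²S), with the isotope masses and natural abundances shipped in
`inst/extdata/element_isotopes.tsv` and exposed via `isotope_constants()`.
The natural ¹⁵N abundance is pinned at 0.003663 and the ¹⁵N–¹⁴N mass
difference at 0.9970349 Da.

Two conventions coexist for the labeled mass shift, deliberately:

* `n15_mass_adjustment(pep, 0.95)` returns **0.95 Da per nitrogen atom** —
  the classic search-engine parameterization (for "AK", 3 × 0.95 =
  2.85 Da).
* `n15_mass_adjustment(pep, 0.95, exact = TRUE)` returns
  0.95 × 0.9970349 Da per nitrogen — the physically exact expectation.

The difference is ≈ 0.3% of the shift, i.e. 30–40 ppm on a typical tryptic
peptide at 95% enrichment. Search engines with wide tolerances absorb the
approximation; a 10 ppm pipeline does not. The generator therefore writes
physically exact labeled masses, and `run_pipeline()` assigns label mode
with `exact_shift = TRUE` by default, while `match_labeled_mode()` defaults
to the approximate convention for parity with classic search configuration.

Isotope envelopes are computed by convolving per-element isotopologue
distributions, with the nitrogen heavy-isotope probability as a free
parameter. Truncation to `n_peaks` during convolution is exact for the
retained peaks (mass only flows upward), and intensities are renormalized
afterwards. Classification of an observed envelope (natural vs enriched)
uses cosine similarity against the two theoretical templates, with ties
resolved to natural; this stands in for the envelope-deconvolution tools
real pipelines use upstream and is validated to ≥ 99% accuracy at
multiplicative noise σ = 0.05 for peptides with at least five nitrogens.

## Identification rules and their boundary semantics

* **FDR threshold**: the lowest score `s` with
  `#{decoys ≥ s} / #{targets ≥ s} ≤ fdr`; all targets scoring `≥ s`
  (ties included) are accepted. This is the plain decoy/target ratio, not a
  rescoring procedure.
* **Protein inference**: a gene is identified iff ≥ 2 distinct peptides map
  to it and ≥ 1 maps uniquely. Genes with ≥ 2 shared peptides and no unique
  one are reported separately as *ambiguous* — they are real signals that
  cannot be placed in one paralog, and discarding them silently would bias
  family-rich proteomes.
* **Fractional counting**: a PSM whose peptide occurs in `n` genes adds
  `1/n` to each, so total spectra are conserved over mapped PSMs. Accepted
  false matches that map to no fixture gene contribute nothing.
* **"Region in the genome"** is operationalized as "gene": the data model
  has protein sequences, not genome coordinates.
* **Induced female proteins** must (i) have secretion probability
  strictly above 0.90 — missing predictions fail the criterion,
  conservatively, with a logged message; (ii) be absent from the unmated
  control's identifications; (iii) not be identified as male-derived. Note
  the control can only exclude what it actually detects: a constitutive
  female protein missed by the single control run can still slip through,
  in simulation as in reality.

## Quantification

NSAF for gene *g* is `(count_g / length_g) / Σ_j (count_j / length_j)`,
with counts summed across the four mated biological samples by default
(per-sample NSAF is the same formula on one sample's counts). Genes with
several annotated transcripts use an effective length; the default rule is
the median (even-length lists average the central pair), with shortest,
longest, and seeded-random alternatives provided — on the synthetic data
the choice does not change any group comparison, and tests assert as much.
For group contrasts NSAF values are arcsine-square-root transformed
(domain-clipped to [0, 1] to guard floating error) and compared with the
Wilcoxon rank-sum test.

## Statistics conventions

* **Wilcoxon rank-sum**: `W` is the Mann–Whitney count of pairs
  `x_i > y_j` plus half-ties (the convention of mainstream statistical
  software). P-values are exact for tie-free samples with
  `min(n, m) ≤ 8`, normal-with-continuity-correction otherwise; fully tied
  data return p = 1.
* **Fisher's exact test** is two-sided by the point-probability rule.
* **Hypergeometric enrichment** restricts the population to annotated genes
  (matching how genome-annotation tools count their denominators) and uses
  a Bonferroni multiplier equal to the number of terms with at least one
  study-set annotation.
* **Likelihood-ratio tests** use a plain chi-square null with df = 2
  (M7 vs M8) and df = 1 (M8a vs M8). The boundary-mixture null would be
  less conservative; plain chi-square was chosen and is documented here
  because the source conventions for these tests vary.

## Evolutionary analysis

`ng86_dnds()` implements Nei–Gojobori (1986) pathway counting with
equal-weight substitution pathways (pathways through stop codons are
excluded unless all are blocked), mutations to stops counted as
nonsynonymous, and the Jukes–Cantor correction. When a proportion of
differences reaches the correction's domain boundary (p ≥ 3/4) the rate is
undefined and returned as `NA`; `dS = 0` likewise flags omega as undefined,
and such records are excluded from rate comparisons with a reason code.
This estimator exists to generate and check synthetic rate structure; ML
codon-model fitting is consumed as input tables, not re-implemented.

Quality control follows the printed boundary semantics exactly: pairwise
records are removed when aligned codons < 100, dN > 1 (dN = 1 kept), or
dS ≥ 0.381 (0.381 removed); five-species fits are removed when the maximum
pairwise dS exceeds twice the genome median (exactly 2× kept).

The five-criterion verdict for recurrent positive selection requires:
M8 over M7 at p < 0.01 (df 2); M8 over M8a at p < 0.01 (df 1); the extra
M8 ω class > 1.1 (strict); ≥ 1% of codons in that class (inclusive); and
≥ 1 FEL-positive codon (inclusive). On synthetic truth the verdict's
type-I rate is bounded by the product of the two LRT sizes (≈ 10⁻⁴,
asserted ≤ 0.01) and recall exceeds 0.95 at effect 4 with 200 genes.

## Directed acquisition

Inclusion windows are `m/z × (1 ± 10⁻⁵)` (10 ppm) by `rt ± 1.5 min`,
closed at their edges, one window per natural-classified, not-previously-
sampled feature, without merging. The schematic instrument model fragments
the `top_n` most intense co-eluting features per scan cycle, prioritizing
inclusion-window features in directed mode, with per-run dynamic
exclusion. The comparison operation reports per-gene spectral deltas
(directed − data-dependent) with median and quartiles.

## Problem sizes and numerical choices

The test suite and examples run the generator at experiment-wide expected
gene abundances of ~25–120 spectra (`meanlog = log(25)` to `log(120)`),
giving 3,000–30,000 PSMs per experiment; multi-seed properties (FDR
control across 50 seeds, plug-share and discovery-curve behavior across
20 seeds) use the lower end of that range. These sizes were chosen as the
smallest at which the asserted proportions are statistically stable.
Envelope truncation uses `n_peaks = N + 4` peaks for an `N`-nitrogen
peptide when both natural and labeled templates must be distinguishable.
All generators take explicit integer seeds and are byte-deterministic per
seed; the pipeline derives stage seeds from a single root seed.

## Known limitations

* The simplified matcher scores are synthetic; no spectral scoring or
  semi-supervised rescoring is modeled.
* No protein-level FDR is computed; the two-peptide rule is the only
  protein-level guard, as in the modeled workflow.
* Enrichment takes annotations as given (pre-propagated); there is no
  ontology-graph handling.
* The acquisition model has no duty-cycle or chromatography physics beyond
  feature retention times.
* Site-model and FEL fitting are consumed as tables; the package tests the
  decision layer above them, not the ML fits themselves.
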