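---
title: "proxidiff: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxidiff: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxidiff)
```

# Scope

`proxidiff` implements the analysis chain of a background-corrected BioID
proximity-labeling experiment and its downstream gene-set stages:
protein-level quantification with a triple-contrast corrected interaction
effect; weighted Kolmogorov–Smirnov gene-set enrichment with a phenotype
permutation null; minimal co-expression module detection with
eigengene–trait correlation; and the set arithmetic that connects an
interactor list to disease-enriched gene sets. A synthetic-data module
generates both data types with known ground truth, so every stage is
exercised and verified offline. This vignette records the models, the
parameters that matter, and the choices made where the design was
genuinely open.

# The five-condition BioID model

The design crosses biotin treatment with bait transfection:

| condition     | bait construct | biotin | carries            |
|---------------|----------------|--------|--------------------|
| `BAG3_Biotin` | bait–ligase    | yes    | t + o + b          |
| `BioID`       | ligase only    | yes    | b                  |
| `BAG3`        | bait–ligase    | no     | o                  |
| `AC16_Biotin` | none           | yes    | b                  |
| `AC16`        | none           | no     | —                  |

with three replicates per condition. In log2 space a protein's intensity
is `baseline + b·[biotin-treated] + o·[bait-transfected] +
t·[BAG3_Biotin] + noise`, where `t` is the true proximity effect, `b` the
biotin/streptavidin background and `o` the response to bait
over-expression. The three group contrasts then have expectations
`t + o` (main), `b` (biotin) and `o − b` (over-expression), and

```
corrected = fc_main − fc_biotin − fc_oe
```

has expectation `t` exactly, for every protein class. This identity is
the reason the biotin-background effect is applied to *all three*
biotin-treated conditions in the simulator, including the free-ligase
condition: free ligase plus biotin produces the same nonspecific
biotinylation background, and with that choice the correction formula is
exactly unbiased under the model — which the test suite asserts (mean
corrected effect over interactors recovers the planted mean within 3
standard errors; artifact classes recover zero).

A protein is *called* an interactor when the main contrast's BH-adjusted
p is below `alpha` (default 0.05) **and** the corrected effect is
positive. Two readings of "positive interaction" are possible — positive
corrected effect or positive raw main fold change — and both are
implemented (`call_interactors(..., positive = "corrected")` is the
default; `"main"` is the alternative). Significance is gated on the main
contrast only: the corrected composite combines four group means across
three contrasts and no variance is propagated for it, so no p-value is
attached to it (see Limitations).

## Quantification conventions

* **Normalization** equalizes sample medians over observed values
  (log2 shift), the standard guard against loading differences. A
  consequence worth knowing: in a bait+biotin condition where a
  substantial fraction of proteins is genuinely enriched, the column
  median itself absorbs part of the enrichment, shifting main-contrast
  fold changes slightly downward. In the full pipeline this acts as a
  small conservative margin — borderline zero-effect proteins are not
  pushed past the positivity gate by noise. The estimator-unbiasedness
  property runs therefore skip normalization (the simulator has no
  loading shifts to remove), while the end-to-end call-rate and FDR
  runs include it, as the pipeline does.
* **Testing** is a pooled-variance two-sample t with
  `df = n_A + n_B − 2`, not a moderated/empirical-Bayes fit: the choice
  is deliberately transparent and exactly matched by a closed-form
  oracle in the tests.
* **Missing data**: no imputation. A protein needs `min_obs` (default 2)
  observed values per group to be testable; untestable proteins are
  flagged and excluded from BH adjustment (which runs over testable
  proteins only, within each contrast). A protein untestable in a
  *correction* contrast has that term treated as 0 with a flag, rather
  than being dropped.
* **Degenerate variances**: both groups constant and equal gives
  `t = 0, p = 1`; both constant but unequal gives the machine-minimum
  positive p with a warning.

# The enrichment engine

Genes are ranked by signal-to-noise
`(mean_case − mean_ctrl) / (sd_case + sd_ctrl)` with each sd floored at
`max(sd, 0.2·|group mean|, 1e-8)`; ties are broken by gene id so reruns
and row permutations give identical rankings. The enrichment score is
the signed maximal deviation of the weighted running sum
(`|metric|^p` increments for hits, uniform decrements for misses), with
weight `p = 1`. The null permutes phenotype labels (seeded); when the
number of distinct label splits does not exceed `n_perm`, the null is
enumerated exhaustively, and on tiny studies the nominal p equals an
exhaustive-enumeration oracle exactly. The nominal p and NES are
sign-matched — each observed ES is compared with, and normalized by,
permuted scores of its own sign. The FDR q is the ratio method: for
`NES* > 0`, the fraction of all permuted NES at least `NES*` divided by
the fraction of observed NES at least `NES*`, clipped to [0, 1] and made
monotone by a suffix minimum from the most extreme score inward
(symmetric for negative scores). A q of exactly 0 is representable and
reported when no permuted score reaches the observed one.

Defaults (ranking metric, `weight_p = 1`, phenotype permutation,
`n_perm = 1000`, set-size bounds 15–500) follow the common desktop-GSEA
conventions, and each is a function argument. The gene universe is the
expression matrix after dropping zero-variance rows. A preranked mode
with a gene-permutation null (`gsea_preranked`) is provided for
externally ranked lists.

Calibration: the ratio-method q is approximately, not exactly,
calibrated. In null simulations (20 random sets, pure-noise expression,
50 seeds) at most one set reaches q < 0.05 in ≥ 98% of seeds, but a
single spurious q < 0.05 set appears in roughly 10% of seeds. Claims
that *no* set will pass are therefore too strong; the tests assert the
at-most-one form.

# Co-expression modules

The chain is unsigned adjacency `|cor|^β` → topological overlap →
average-linkage clustering of `1 − TOM` → static cut → eigengene–trait
correlation.

* **Soft power** is the smallest `β ∈ 1..20` whose signed scale-free fit
  reaches `R² = 0.8`, else the argmax. The fit regresses log10 bin
  frequency on log10 mean connectivity over 10 *equal-width*
  connectivity bins — equal-width, because equal-count bins make the
  bin frequency constant by construction and the regression degenerate.
  A saturated network (all `|r| = 1`) has flat connectivity at every
  power; the fit is then undefined and the smallest candidate power is
  returned with a warning (the choice is immaterial there).
* **Static cut height** defaults to 0.95 on `1 − TOM`. In a TOM
  dendrogram, unrelated genes join near height 1 while co-expressed
  blocks merge far lower (a module with within-module correlation ~0.8
  sits near 0.6), so the informative cut is just below the top. Cutting
  much lower (e.g. at 0.25) shatters realistic networks into
  singletons. Clusters below `min_size` (default 20) are relabeled 0
  (unassigned); surviving modules are renumbered by decreasing size.
* **Eigengene**: first principal component of the standardized member
  submatrix, unit variance, sign-oriented so the mean correlation with
  member genes is non-negative (the decomposition leaves the sign
  arbitrary). Trait association is a Pearson correlation with the usual
  t transform. The oriented eigengene is invariant to gene order; a
  single-gene module's eigengene is that gene's standardized profile.

Dynamic tree cut, module merging, signed networks and robust
correlations are intentionally out of scope — the goal is the minimal
chain that supports the qualitative claim of interest (the module
carrying the bait gene is down-regulated in disease), which the planted
simulations recover (mean adjusted Rand index ≥ 0.8 at replicate noise
0.5; the shifted module's eigengene correlates negatively with
case status at p < 0.01).

# Integration arithmetic

Significance in an enrichment table is strict (`q < 0.05`); exact-zero q
values occur and pass. Venn logic, interactor-to-set mapping
(case-insensitive, uppercased symbols), the ≥ n-protein filter (default
3) and distinct-protein unions are plain set operations, verified
against the packaged two-condition hallmark fixture whose published
counts (26/26 significant, 24 both, 28 either, 15 core sets, 31
cell-cycle proteins, 13 and 9 per-set interactors) reproduce exactly.

The list-overlap test is the one-sided upper-tail hypergeometric
probability `P(X ≥ k)` computed by log-space summation of point masses,
so p-values in the 1e-7 regime keep full precision; the background
defaults to 20,000 (approximately the protein-coding human genome). For
the published 387-vs-382-list configuration with 22 shared proteins the
exact value is 5.96e-06 (expected overlap 7.4). The value printed in the
originating report, 3.69e-07, is not reproducible from the stated
configuration under a standard one-sided hypergeometric; `proxidiff`
reports its exact computation alongside that number and does not force
agreement.

# The synthetic-data generator

`simulate_bioid` emulates: log-normal protein abundance (log2 baseline
~ N(20, 2), the scale of label-free MS intensities), additive class
effects, replicate noise, and intensity-dependent missingness — a cell
drops out with probability `plogis((lod − y)/steepness)`, the
missing-not-at-random behavior of label-free MS. One uniform draw per
cell implements the missingness, so lowering the threshold never adds
missing cells under a fixed seed. Protein classes are mutually exclusive
(no interactor that is also a background binder), which keeps
ground-truth scoring unambiguous; real interactomes mix these roles.

Default effect sizes: `mu_t = 3` (true bait-proximal proteins ~8-fold
enriched over free ligase — streptavidin capture of biotinylated
proximal proteins produces large enrichments, and with only three
replicates and BH correction over thousands of proteins, substantially
smaller effects would rarely reach significance at all), `mu_b = 1.5`,
`mu_o = 1`, each with spread 0.5; replicate noise 0.5 (log2 CV typical
of label-free quantification); 5% interactors, 25% background, 10%
over-expression responsive, 60% null.

`simulate_expression` emulates a case–control myocardial expression
study (default 16 controls vs 86 cases): latent-factor modules
(`x = loading · factor + noise`, loadings N(1, 0.8) across members,
unequal module sizes — the heterogeneity matters, because equal-loading
equal-size blocks produce a two-point connectivity distribution that no
soft power fits well) with optional per-module case shifts, plus planted
gene-set mean shifts in cases.

What passing tests do **not** show about real data: no peptide-level
effects, shared-peptide ambiguity, batch effects, or correlated
backgrounds; classes are disjoint; expression noise is Gaussian and
homoscedastic. The simulations validate the *statistical machinery*
under its stated model, not the biology of any particular data set.

# Properties of the call rule worth knowing

Because no significance test is applied to the corrected composite, an
artifact protein that reaches main-contrast significance is rejected
only by the positivity gate, and its corrected effect is symmetric
around zero — so roughly half of significant artifact proteins pass the
gate. The correction therefore approximately *halves* artifact calls
relative to the naive rule (and removes their systematic positive bias);
it does not eliminate them. Under the default simulation the empirical
FDR of corrected calls is ~0.06 at `alpha = 0.05` (within the 1.5×
budget) with sensitivity ~0.3; regimes with strong, frequent
over-expression responses will exceed that. Propagating variance across
the three contrasts (or SAINT/CompPASS-style probabilistic scoring)
would address this and is deliberately out of scope.

# Problem sizes and seeds

The test suite and acceptance script run entirely on simulated and
packaged data at desk scale: 200–2000 proteins, 15 samples for BioID
runs (20 seeds for property averages); 300–800 genes, 12–102 samples for
expression runs; 50 seeds for null-calibration loops; 10 seeds for
module-recovery loops; 200–1000 permutations for enrichment. All
randomness is seeded; the acceptance script derives every stream from
its `--seed` argument.

# Known limitations

* The corrected effect has no attached uncertainty; calls inherit
  error control from the main contrast only (discussed above).
* The ratio-method FDR q is approximately calibrated (discussed above).
* Median normalization assumes most proteins are unchanged per
  condition; in designs where this fails, normalization against a
  designated null set would be preferable.
* The static cut is a deliberate simplification of dynamic tree cut;
  nested or close modules will merge or fragment near the cut height.
* Published external quantities that require the original raw data (the
  original 387-protein list, per-set NES/q values from the real
  expression study, its fold changes) are represented by packaged
  fixtures and are *inputs* here; the package reproduces the arithmetic
  on top of them, not the values themselves.
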