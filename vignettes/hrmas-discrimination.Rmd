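---
title: "Discriminating two-class 1D NMR metabolomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating two-class 1D NMR metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodisc)
```

## The problem

`metabodisc` implements a complete chemometric workflow for deciding, from
1D ^1^H NMR spectra of intact tissue, which of two groups a sample belongs
to and which resonances drive the separation. The motivating system is the
gonadal metabolome of two sympatric Mediterranean sea urchins:
*Arbacia lixula*, whose spectra are dominated by osmolytes and methylated
amines (betaine, taurine, sarcosine, TMA, TMAO, carnitine, creatine,
malonate, methylmalonate, uridine, xanthine), and *Paracentrotus lividus*,
dominated by free amino acids and C1/methylotrophic compounds (lysine,
glycine, glutamine, formaldehyde, methanol,
3-carboxypropyl-trimethylammonium) together with broad lipid envelopes.
Because raw HR-MAS spectra of this kind are rarely depositable, the package
ships a synthetic-spectrum generator with known ground truth; every claim
the test suite makes about the workflow is made against cohorts whose
discriminant metabolites are known by construction.

## The synthetic cohort generator

`simulate_cohort()` renders each metabolite as 1-3 Lorentzian lines (the
natural NMR line shape) at HMDB-style reference positions stored in a
packaged table; line width defaults to 0.003 ppm FWHM. Species-biased
metabolites are scaled by $2^{\pm e/2}$ with `log2_effect` $e$, so the two
class geometric means straddle a shared baseline concentration and the
injected contrast is symmetric in log space. The two species panels are
given equal expected total area (a `base_conc` column balances the
11-compound osmolyte panel against the amino-acid/lipid panel), so
total-area normalization cannot leak class membership through panel-size
imbalance. On top of the signal the generator adds, per spectrum:
log-normal biological variation (`biological_cv`, default 0.2), a global
chemical-shift jitter (`shift_jitter_sd_ppm`, default 0.0015), a smooth
random fourth-order polynomial baseline (`baseline_amplitude`, default
0.2) and Gaussian point noise (`noise_sd`, default 0.5, i.e. a
signal-to-noise ratio of a few hundred for a unit-concentration singlet —
typical of CPMG HR-MAS data). Defaults define the reference study
conditions used throughout: 12 spectra per species and `log2_effect = 2`,
a strong but realistic four-fold contrast.

Each Lorentzian is rescaled so that its trapezoidal integral on the
discrete axis equals concentration × relative area exactly; this absorbs
quadrature error and the mass truncated at the axis ends, and makes
area bookkeeping (and the conservation tests) exact rather than
approximate. Randomness flows from one root seed through fixed-offset
per-spectrum substreams, so cohorts are bit-reproducible and insensitive
to evaluation order.

What the generator does *not* emulate: multiplet fine structure (peaks are
1-3 independent lines, not coupled spin systems), peak-position drift that
varies across the spectrum (jitter is a global shift), pH-dependent shift
changes, and spectral artefacts (phasing errors, water-suppression
residuals beyond a fixed exclusion band). Passing tests therefore show
that the chemometric machinery behaves correctly under controlled,
NMR-like conditions — not that it is robust to every artefact of real
acquisitions.

## Preprocessing

Spectra are integrated into uniform buckets (default 0.01 ppm) by a
cumulative-trapezoid scheme that is exactly linear in the spectra; the
default axis places bucket centres on the conventional 0.01-ppm reporting
grid. Residual water (4.7-5.0 ppm) and the TSP reference region
(±0.05 ppm) are excluded by default. Rows are normalized to unit total
area. Pretreatments follow the usual chemometric conventions: mean
centring for the main model (it preserves relative signal amplitudes,
which keeps VIP and target-projection profiles interpretable), Pareto
scaling inside the Monte-Carlo sub-models, auto scaling available. Scaling
parameters are always estimated on training data and applied frozen to
held-out data.

## PLS-LDA

The main model is PLS1 by NIPALS on the centred matrix with $A = 3$ latent
variables: per component $w \propto X'y$, $t = Xw$, $p = X't/t't$,
$r = y't/t't$, deflating $X$ by $tp'$ and $y$ by $tr$. Class labels are
encoded +1 (*A. lixula*) and −1 (*P. lividus*). Classification is by a
two-class pooled-covariance LDA on the score matrix; the boundary is the
zero set of the affine discriminant function, and its restriction to the
LV1/LV2 plane is exported for score plots, together with per-species 95%
Gaussian ellipses scaled by the $\chi^2_2$ quantile. Singular pooled
covariances (possible on tiny sub-models) receive a ridge of
$10^{-8}\,\mathrm{tr}(S)/A$.

Variable diagnostics use the standard Wold VIP
($\sum_j \mathrm{VIP}_j^2 = p$) and Kvalheim-style target-projection
loadings: the data are projected onto the normalized PLS regression
vector and the loadings of that single predictive component are reported.
Both conventions are stated explicitly because the field uses the names
loosely.

Performance is estimated by stratified 5-fold cross-validation repeated
20 times with pretreatment re-estimated inside every fold; error,
per-class sensitivity/specificity and AUC are computed from the pooled
held-out decision values. AUC uses midranks, so it is invariant under
monotone transforms and handles ties by the 0.5 convention. The label
permutation test reports the add-one estimator
$p = (1 + \#\{\mathrm{AUC}_{perm} \ge \mathrm{AUC}_{obs}\})/(n_{perm}+1)$.

## Subwindow Permutation Analysis

SPA populates $N$ Monte-Carlo PLS-LDA sub-models, each built on a
stratified random 70% calibration split and $Q = 15$ randomly drawn
buckets, Pareto-scaled, with the number of latent variables chosen per
sub-model by internal $K = 3$-fold cross-validation (smallest model on
ties). The sub-model's misclassification rate on its held-out 30% is the
*normal* error of every variable it contains; permuting one variable's
values across the held-out block (model fixed) gives that variable's
*permuted* error. Per variable, `DMEAN` and `DSD` are the mean and SD
differences (permuted − normal), the p-value is the one-sided rank-sum
probability that permuted errors exceed normal errors (exact by full
enumeration when both samples have ≤ 8 values, tie-corrected normal
approximation otherwise), floored at $1/(N+1)$, and
$\mathrm{COSS} = -\log_{10} p$, with COSS > 2 (p < 0.01) declared
significant.

Three design choices matter in practice and are the package's own:

* **Latent-variable search bound.** The internal search runs over
  $1 \ldots \min(Q,\, n_{cal}-K,\, \texttt{max\_lv})$ with
  `max_lv = 5`: on calibration sets of ~17 samples, sub-models with more
  than a handful of components only fit noise, and the bound keeps the
  search affordable.
* **Permutation replicates.** Each variable is permuted
  `n_perm_rep = 5` times per sub-model. A single permutation of a short
  test block can, by luck, swap values within a class and leave
  predictions unchanged; replicates average that luck out of the
  permuted-error sample. Null calibration with shuffled labels (part of
  the test suite) shows the false-positive fraction at COSS > 2 stays
  far below the nominal 1%.
* **The variable pool is the full binned matrix.** It is tempting to
  screen out empty baseline buckets first, but on strong-contrast cohorts
  almost every peak-region bucket is class-informative; sub-models drawn
  from such a pool contain many redundant discriminators, and permuting
  any single one no longer degrades prediction (normal and permuted
  errors are both zero, and every p-value collapses towards 1). With the
  full matrix, most draws are baseline buckets, an informative bucket is
  usually the dominant weight-carrier of its sub-model, and its
  permutation visibly breaks the sub-model. The rank test then needs
  $NQ/p \approx 15$ draws per variable at $N = 1000$ — which is why SPA
  is run at the full published iteration count rather than scaled down;
  at $N = 200$ on a 0.01-ppm matrix each variable is drawn ~3 times and
  p < 0.01 is arithmetically out of reach for any rank test.
  (`filter_bins()` remains available as a screening utility.)

## Targeted integration and univariate comparison

Windows of ±0.015 ppm around each metabolite's dominant line are
integrated on the total-area-normalized spectra. Group summaries follow
the Tukey boxplot convention with linear-interpolation quartiles; the
between-species test is the two-sided Mann-Whitney test (exact for small
groups), with Benjamini-Hochberg adjusted values reported alongside raw
p-values — strong effects keep their headline calls either way, and the
adjusted column is the honest default for marginal ones.

## Pathway over-representation and topology

Compound names are mapped case-insensitively through a packaged synonym
table to KEGG-style identifiers; unmapped names are returned, never
dropped silently. Enrichment uses the upper hypergeometric tail
$P(X \ge k)$ against the universe of all compounds in the loaded library,
with Holm and Benjamini-Hochberg adjustments across pathways. Topology
impact is the sum of betweenness centralities of hit compounds, each
normalized by the pathway maximum, divided by the sum over all pathway
compounds; graphs without through-traffic score 0.

The packaged pathway library is a **synthetic, KEGG-modelled fixture**
(`pathway_library_synthetic.json`): real KEGG compound identifiers for the
observed metabolites, synthetic filler members elsewhere, with pathway
sizes and memberships arranged to match the biology of the motivating
system (e.g. glycine/serine-threonine metabolism with 34 members carrying
betaine, sarcosine and glycine; taurine/hypotaurine metabolism with 8).
Because the universe is library-dependent, p-values and FDRs from this
fixture are internally consistent but not comparable to a live KEGG or
MetaboAnalyst run; hit counts are. The *A. lixula* pathway panel carries
glycine alongside the osmolytes because the betaine → sarcosine → glycine
demethylation cascade anchors that species' C1 signature, even though the
free glycine pool itself is higher in *P. lividus*.

## Numerical conventions and degenerate inputs

* Buckets are half-open `[hi, lo)` intervals in descending ppm, fixing
  boundary ownership; binning is exact for piecewise-linear spectra.
* Zero-variance columns scale by 1 and are flagged, not dropped.
* Rank-sum ties use midranks; the large-sample branch applies tie
  correction and a 0.5 continuity correction; identical samples give
  p ≥ 0.5.
* The COSS floor $1/(N+1)$ keeps scores finite at the Monte-Carlo
  resolution.
* Variables never drawn into any sub-model are reported with p = 1,
  COSS = 0 and a `never_sampled` flag.
* Cross-validation requires `folds` ≤ the smaller class size so every
  training fold keeps both classes.

## Problem sizes used in the test suite

The suite validates the workflow at the reference conditions (24 spectra,
16384-point axis, 1008 buckets after exclusions). Monte-Carlo-heavy
properties use deliberately chosen sizes: SPA power runs at the published
$N = 1000$ over 20 cohort seeds; null calibration uses 50 shuffled-label
runs at $N = 300$, which already resolves p < 0.01 per variable; property
loops (effect monotonicity, parameter recovery) use a 4096-point axis and
0.02-ppm buckets. These sizes are the smallest at which the respective
statistical claims are meaningful, and they keep the default test run in
the minutes range.

## Known limitations

* PLS1 with a single two-class contrast only; no multi-class extension.
* No resonance assignment: windows and panels come from the template
  library, not from the data.
* Global shift jitter only; no segment-wise alignment (icoshift-style
  warping) is implemented.
* The pathway fixture is frozen; live KEGG/MetaboAnalyst ingestion is out
  of scope by design.
* Monte-Carlo variable selection on fewer than ~20 samples inherits the
  usual instability of sub-sampling methods; COSS values near the
  threshold should be read as a ranking, not as calibrated significance.
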