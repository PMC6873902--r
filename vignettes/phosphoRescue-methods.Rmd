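---
title: "phosphoRescue: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosphoRescue: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoRescue)
```

## The setting

The package analyzes feature-level label-free intensities from a 2 × 4
factorial mouse design: genotype (WT, TG — transgenic *Dyrk1A*
overexpression) crossed with treatment (untreated, green tea extract,
environmental enrichment, or both), five biological replicates per cell.
Two data layers share one long table format, discriminated by
`feature_kind`: protein abundances and phosphopeptides (which
additionally carry a site position, central residue, localization
probability and flanking sequence window).

## Differential abundance

### Model

Each feature is modeled independently on the log2 scale with the
(genotype × treatment) cell as a single fixed factor:

$$y_{ij} = \mu_{c(i)} + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma^2)$$

estimated by OLS on every observed sample of the feature. A contrast is
a signed combination of cell means; its standard error uses the residual
variance pooled over **all** cells in which the feature was observed
(degrees of freedom $\sum_c (n_c - 1)$), and significance is a
two-sided t test. This is the balanced-design reduction of the
mixed-effect family commonly used for such data: with one animal per
sample and a single MS run per sample there is no replicate structure
left for a random effect to absorb, so the cell-means OLS is exact and
admits a closed-form oracle (the estimate is literally the difference of
cell means), which the test suite exploits.

Assumptions worth stating: Gaussian homoscedastic noise on the log2
scale within a feature, independence across samples, and no
between-run normalization (the simulation produces normalized data;
real inputs are expected normalized upstream).

### Missingness, presence/absence, filters

No imputation is performed anywhere. A feature is *quantifiable* in a
condition only when observed in ≥ 3 of 5 replicates (≥ 2 when the
group retains only 4 replicates after quality control). For a pairwise
comparison, a feature quantifiable on exactly one side is called
`present_only` / `absent_only` and joins that side's list qualitatively,
with no fold change (an `NA` sentinel, never ±Inf). Replicate QC removes
samples observing fewer than half the per-kind median feature count.
Phosphopeptides with localization probability < 0.5 and proteins on the
blood-contaminant list are removed up front. Zero intensities are
treated as missing (log undefined) and counted in the read log.

Benjamini–Hochberg adjustment is applied within each contrast across its
testable features (the convention of adjusting within comparison);
calls require `adj p < 0.05` *and* `|log2FC| > 0.3`. Both thresholds are
configurable (`alpha`, `lfc` in the pipeline config).

## Rescue scoring

With genotype gap $g$ (log2FC of TG.NT − WT.NT) and treatment gap $t$
(log2FC of TG.T − WT.NT), the recovery fraction is $f = (g - t)/g$,
dimensionless: 1 is exact restoration of the untreated-WT level, 0 is no
treatment effect, values above 1 overshoot, negative values widen the
gap. Class boundaries — rescued $[0.5, 1.5]$, overcorrected
$(1.5, \infty)$, not sufficiently rescued $[-0.5, 0.5)$, impaired
$(-\infty, -0.5)$ — partition the line; the interval endpoints at 0.5
and 1.5 are closed on the rescued side, reading "from 50 to 150%"
inclusively. Only features that pass the genotype-contrast call are
scored (this also keeps $|g| > 0.3$, bounding the denominator away
from 0). The treatment gap is taken directly from the fitted TG.T −
WT.NT contrast rather than summing two estimates; the algebraic identity
$t = g + \mathrm{log2FC}(TG.T - TG.NT)$ is verified by a test on
noiseless cell means, not used in computation.

Presence/absence features have no finite fold change; they are scored by
a qualitative state flip: a feature uniquely present in TG.NT counts as
rescued under a treatment exactly when it is absent again under that
treatment (and symmetrically for uniquely-absent features). The
impairment analysis mirrors the recovery formula with the reversed
baseline contrast (WT.NT − TG.NT) to quantify treatments pushing WT
levels toward the TG state.

## Network analysis

Seeds are the union of proteins dysregulated in abundance and proteins
owning dysregulated phosphopeptides (`change_kind` records which, or
`both`). Expansion adds all direct neighbors in the background graph
(edges kept only above the confidence threshold, strict `> 0.9`) and
every induced edge. Edge enrichment is the exact Poisson upper tail with
the expectation `(node pairs) × (background density)`, the density being
computed over the universe of *detected* proteins present in the
background — the "expected" count mirrors the STRING-style enrichment
contract.

Degree distributions are fit on the full support $k \ge 1$ (no lower
cutoff search) with zero-truncated discrete ML for four families:

* power law $p(k) = k^{-\alpha}/\zeta(\alpha)$ (Riemann zeta
  normalization, $\alpha$ by 1-D optimization on $[1.01, 10]$);
* Poisson, truncated at zero ($\lambda$ by 1-D optimization);
* exponential = geometric on $k \ge 1$ (closed-form MLE);
* lognormal discretized by probability mass on integer bins
  $(k-\tfrac12, k+\tfrac12]$, renormalized to $k \ge 1$
  (Nelder–Mead from moment-of-log starting values, with a hard floor of
  1e-300 on bin masses to keep the likelihood finite in the far tail).

The selected family minimizes BIC. For equal parameter counts this is
just the higher likelihood; the dimension penalty matters because an
unpenalized (or AIC) comparison prefers the 2-parameter lognormal over
the true 1-parameter power law on a non-vanishing fraction of samples —
BIC's consistency is what lets simulation tests demand recovery of the
generating family. All four log-likelihoods, AICs and BICs are kept on
the fit object.

Hubs are nodes with fitted tail probability $P(K \ge k) < 0.05$
(computed from the selected family, not the empirical tail, so
low-degree nodes also receive well-defined p-values), ordered by degree
descending with lexicographic tie-break on the protein id. Subset
statistics use a permutation test — random same-size node subsets,
without replacement, p-value $(1 + \#\{perm \ge obs\})/(n_{perm}+1)$,
which never returns 0. Fit degeneracy (all degrees equal) is an explicit
error instructing use of the empirical tail.

## Motifs

Windows are $2h+1$ residues centered on the phosphosite (default
$h = 7$, the common 15-mer for phospho-logos), padded with `X` beyond
protein termini. Position frequency matrices exclude padding from
denominators so terminal sites do not dilute columns; information
content per column is $\log_2 20 - H$ bits. Consensus patterns are
anchored positional constraints, not free regular expressions: `PXSP`
means P at −2, anything (but never padding) at −1, serine center, P at
+1; `RPX(S/T)P` adds R at −3 and accepts S or T centrally. A pattern
without a phospho-acceptor center token is rejected.

## Behavior

The discrimination index is $DI = (TN - TF)/\text{total} \times 100$.
Group effects use the same cell-means machinery as the proteomics layer:
seven contrasts (TG.NT vs WT.NT; each treatment vs untreated within each
genotype), pooled-variance t statistics, **Holm** adjustment over the
family of seven. The single-step max-t adjustment used in comparable
analyses requires multivariate-normal integration; Holm is deterministic
and conservative, and is documented here as this package's choice. The
behavioral PCA standardizes DI, % time on novel and familiar objects
(TN/total and TF/total × 100), distance, and spontaneous alternation;
PC1's sign is fixed so the DI loading is positive ("higher PC1 = better
learning"). Prototype animals are drawn per group from inside
$[Q_1 - 1.5\,IQR,\ Q_3 + 1.5\,IQR]$ (fences per group, quartile type 7),
then sampled without replacement under the configured seed.

## Correlation and enrichment

Feature-versus-PC1 association uses Spearman correlation with average
ranks and pairwise-complete pairs; features with < 3 pairs or a constant
vector are skipped and counted. The screening threshold `|rho| > 0.4`
is a plain cutoff (configurable); at 10 animals the null law of the
Spearman statistic is wide (about a quarter of null features exceed
0.4 in absolute value), so the screen is a candidate filter, not a
significance test — the full rho distribution is exported for
inspection. Set overlaps use the upper-tail hypergeometric (one-sided
Fisher), odds ratio from the 2 × 2 table, and the Szymkiewicz–Simpson
coefficient $|A \cap B| / \min(|A|, |B|)$; the background universe is
the detected features of the relevant layer, phosphopeptide sets being
collapsed to protein ids first. Pairwise overlap matrices report raw
p-values; annotation-term enrichment applies BH across terms.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
every downstream property is tested under.

* **Design**: 2 genotypes × 4 treatments × 5 replicates (40 samples).
* **Intensities**: feature baselines $N(20, 2^2)$ on the log2 scale,
  replicate noise sd 0.25 — a typical label-free coefficient of
  variation; the paper-scale default of 1,000 proteins and 600
  phosphosites keeps a full run under a minute on one core.
* **Genotype effects**: a configurable fraction (default 10%) of
  features receive ±1 log2 units (random sign).
* **Treatment effects**: per affected feature and treatment, a rescue
  class is drawn from `recovery_mix` (default 50% rescued, 30% not
  sufficiently rescued, 10% overcorrected, 10% impaired) and a true
  recovery fraction $f$ uniformly inside that class interval; the
  planted TG treatment effect is $-f \cdot g$, so the noiseless gaps
  reproduce $f$ exactly. Fractions are inset `class_margin = 0.3` from
  the class boundaries: by the delta method the sampling sd of
  $\hat f = (\hat g - \hat t)/\hat g$ under the default design is about
  0.2 (the two gaps share the WT.NT mean, and the ratio inflates the
  variance), so truths closer than one sampling-sd to a boundary carry
  no recoverable class label; the margin of 1.5 sampling-sd makes
  planted classes identifiable, which any truth-recovery test
  presupposes.
* **Missingness**: logistic in the true log2 intensity,
  $P(\text{missing}) = \text{logit}^{-1}(s \cdot (m - x))$ with
  steepness $s = 1.5$ and midpoint $m = 16$; $s = 0$ disables it.
  "Absent/low abundant" status is therefore *induced* — only the
  downstream observation rule creates presence/absence calls.
* **Contaminants**: 2% of proteins flagged as blood contaminants.
* **Phosphosites**: central residue S/T/Y at 0.8/0.17/0.03; localization
  probability Beta(4, 1) (about 6% below the 0.5 filter); among
  TG-upregulated serine sites a configurable fraction (default 0.4)
  carries proline at +1, 30% of those proline at −2, and 2% of
  TG-upregulated S/T sites the full R(−3)/P(−2)/P(+1) context.
* **Background network**: preferential attachment (m = 2, two distinct
  targets per new node, degree-proportional), giving exactly $2N-3$
  edges and a heavy right tail; edge scores uniform in [0.9, 1];
  optional explicitly wired hub nodes for hub-recovery tests.
* **Behavior**: per-animal latent learning factor shared by DI (loading
  0.7 of the DI variance, within-group sd 12 DI units), distance and
  alternation; exploration times are constructed from the DI so the DI
  is exactly recomputable. Default group means encode a TG baseline
  deficit (0 vs 40) mostly restored by the green-tea-containing arms.

What the generator does **not** emulate: peptide-to-protein roll-up
ambiguity, between-run batch effects and normalization error,
correlated features (co-regulation), heavy-tailed or
intensity-dependent variance, raw spectra. Passing tests therefore
establish correctness of the inference chain under a clean generative
model, not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Poisson tails via the regularized incomplete gamma (`ppois`), exact to
  brute-force pmf summation within 1e−10 in the tested range.
* Hypergeometric tails via `phyper`, exact to brute-force enumeration
  within 1e−10 for backgrounds up to 60.
* Noiseless cells give zero residual variance: t statistics become
  ±Inf and p-values 0/NaN; tests on exact data assert the estimate, not
  the p-value, except where the contrast is nonzero.
* Empty inputs are errors with named causes (empty table after
  filtering, empty seed set, empty window list); self-loops in edge
  lists are dropped with a warning; duplicate undirected edges are
  collapsed keeping the first score.
* Ties in hub ordering break lexicographically; quantile fences use R's
  default type-7 quantiles.
* Problem sizes in the test suite (chosen to keep a full run in tens of
  seconds on one core): 1,000-feature proteomes for parameter-recovery
  and null-calibration checks, 500-node degree samples × 50 replicates
  per family for model-selection recovery, 500 null subsets × 199
  permutations for permutation-test calibration.

## Known limitations

* No uncertainty on the recovery fraction: classification is a point
  decision, and features near class boundaries are intrinsically
  unstable (the generator's margin acknowledges exactly this).
* The Spearman screen has no error control at small n (see above).
* Degree-fit families are fit without a lower-cutoff (xmin) search; a
  distribution that is power-law only in its extreme tail will be
  attributed to the best whole-support family, usually the lognormal.
* Phosphopeptide-to-protein collapsing treats any dysregulated site as
  marking its protein; opposing sites on one protein are not
  reconciled.
* The pipeline assumes upstream normalization and a single MS run per
  sample; peptide-level roll-up is out of scope.
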