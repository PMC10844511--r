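---
title: "gonodyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gonodyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gonodyn` quantifies how sex-enriched gene expression is built during
gonadal sex differentiation: per sex, between the onset (T1) and the end
(T2) of differentiation, and comparatively across species. This vignette is
the package's own account of the statistics it implements, the choices that
were genuinely open, and what its green tests do and do not establish.

## 1. The analysis model

### 1.1 Within-sex stage contrasts

Each species contributes a gene × sample matrix over a 2 (sex) × 2 (stage)
design with ≥ 2 replicates per cell. Differential expression between T1 and
T2 is computed separately per sex, then once more between the sexes at T2.

**Intensity platform** (log2-scale, pre-normalized, microarray-like).
Gene-wise two-group comparison with empirical-Bayes variance moderation.
With pooled residual variance $s_g^2$ on $d_g = n_1 + n_2 - 2$ df, the
posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $\tilde t_g = \Delta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ is referred
to $t(d_0 + d_g)$. The hyperparameters $(d_0, s_0^2)$ are fit by matching
the empirical mean and variance of $\log s_g^2$ to their theoretical
digamma/trigamma moments (`fit_variance_prior()`); the trigamma inverse is
solved by Newton iteration to a relative tolerance of 1e-8. When the excess
variance of $\log s_g^2$ is non-positive the prior df is infinite (full
shrinkage); if the fit degenerates, the engine falls back to unmoderated
variances with a warning. `d0 = 0` reproduces the ordinary pooled t exactly
(a test asserts this to 1e-10), and the whole route is checked against
limma's `lmFit`/`eBayes` on simulated data.

**Counts platform** (RNA-seq-like). Median-of-ratios size factors
(reference = zero-free genes), then a gene-wise negative-binomial GLM
(log link, offsets $\log s_j$, intercept + group indicator) fit by IRLS
with explicit 2×2 normal equations, vectorized across genes (25 iterations
max, coefficient tolerance 1e-8, linear predictor clamped to ±30 to avoid
overflow). Dispersion is the per-gene method-of-moments estimate on
normalized counts, $\hat\alpha_g = (v - \bar{1/s}\,m)/m^2$ floored at 1e-8
— deliberately the simplest defensible estimator; shrinkage toward a
mean–dispersion trend is *not* applied to the test statistic, and numerical
identity with published count-model packages is not promised. The Wald
statistic $z = \hat\beta_1/\mathrm{SE}$ is referred to $t(n-2)$ rather than
the asymptotic normal: with noisy moment dispersions at realistic replicate
numbers the normal reference is anticonservative, while the $t$ reference
keeps the type-I error at or below the nominal level at every design size
(the acceptance report recomputes this on 20,000-gene all-null
simulations). The cost is conservatism at 2–3 replicates; this is the
package's deliberate trade.

Genes with total count below `min_total_count` (default 10), all-zero rows,
or a zero-count group are reported untested with missing p-values.

### 1.2 Outlier flagging and independent filtering

**Cook's distance.** Per observation,
$D = r^2 h / (p (1 - h)^2)$ with standardized Pearson residual $r$, hat
value $h$ from the weighted design, and $p = 2$ coefficients. A gene is
flagged (p-values removed) when any sample in a group with ≥ 3 replicates
exceeds the cutoff 19.17; two-replicate groups cannot single out an outlier
and never flag. One subtlety the implementation had to resolve: a count
outlier inflates its *own* gene's moment dispersion estimate and would mask
itself. Cook's distances are therefore computed from a refit under a
robust mean–dispersion trend $\alpha(\mu) = a_1 + a_0/\mu$, estimated with
median-based statistics that no single gene can drag
(`fit_dispersion_trend()`). The Wald test itself keeps the per-gene
dispersion.

**Independent filtering.** Base-mean quantile thresholds over the grid
0%, 1%, …, 95%; genes below a candidate threshold are removed and the
number of BH rejections at `if_alpha = 0.1` recomputed; the smallest
threshold maximizing rejections wins (so filtering never rejects fewer
genes than no filtering). Filtered genes keep raw p but lose the adjusted
p. BH adjustment itself is the classic step-up, monotone and capped at 1,
with missing values excluded from the number of tests.

### 1.3 DEG calling and the fold-change threshold

A DEG is a tested gene with $|\log_2 \mathrm{FC}| \ge$ `fc_threshold` and
BH-adjusted p < `alpha` (defaults 1.5 and 0.05). The threshold's scale is
ambiguous in common usage — "FC ≥ 1.5" can mean 1.5 log2 units ($2^{1.5}$ ≈
2.8-fold) or a linear 1.5-fold (0.585 log2 units). The default follows the
signed log2 reading ("1.5 or lower than −1.5"); `fc_scale = "linear"`
exposes the other interpretation rather than hiding the ambiguity.

### 1.4 The fold-change plane and mechanism classes

Each gene analyzed in both sexes becomes a point with the female T1→T2
log2FC on X and the male on Y. Classification:

* **NONSIG** — not a DEG in either sex;
* **MEG / FEG** — a DEG in ≥ 1 sex whose between-sex contrast at T2 is
  significantly male- / female-enriched (same engine and thresholds);
* **SHARED** — a DEG in ≥ 1 sex without significant T2 sex enrichment.

The operational MEG/FEG rule was genuinely open: defining "grey" as
"significant in both sexes" would misclassify genes that rise in both sexes
yet end up strongly sex-enriched (the mouse *dmrt1* pattern). The T2
between-sex test resolves this; an alternative rule — sign of
$\mathrm{FC}_M - \mathrm{FC}_F$ with a log2 margin, no extra test — is
available via `rule = "fc_margin"`.

Mechanisms for a MEG: `both` when male-up and female-down are both
significant; `own-up-only` when only male-up is; `opposite-down-only` when
only female-down is; FEGs mirrored. Because the T2 contrast is a separate
test, a rare residual case exists (e.g. a MEG whose only significant
per-sex change is downward in males, the female dropping more but below
significance); such genes are attributed to the sex carrying the
significant change so that the five summary categories — males up/down,
females up/down, both sexes — remain an exact partition of the DEGs, a
property the tests enforce. Each MEG with both components significant
counts once, under the upregulated-in-males column: the published
per-category tables sum exactly to their totals, implying disjoint columns.

The activation/repression percentages divide, within MEGs, the
upregulated-in-males count by all MEGs (and the female-downregulation
complement), mirrored for FEGs; zero denominators give NA.

### 1.5 Cross-species comparison

*Harmonization.* Native symbols map through an optional ortholog/alias
table (species-specific rows beat `*` global aliases; lookups are
case-insensitive; unmapped ids fall back to uppercase with a warning
count). Probes collapsing to one symbol keep the probe with the largest
max(|FC_F|, |FC_M|) among its *significant* changes — the probe a
top-gene screen would see — falling back to the largest base mean (largest
|FC| if base means are absent). Harmonization is idempotent.

*Key panel.* Defaults to amh, sox9, dmrt1 (male trio) and cyp19a1, foxl2,
fst (female trio); a gene is panel-reportable when significant in ≥ 3
species in at least one sex (the species count is taken per sex and the
best sex decides — the looser "any sex per species" reading was rejected as
it conflates the two sexes' evidence). Across-species FC means and sample
SDs (n−1) use the *estimated* FCs of all species where the gene is present,
including non-significant estimates — they are estimates, not zeros;
open-symbol plotting conventions make them visible, and zero-substitution
would bias SDs downward.

*SD sex-difference test.* No standard test exists for "is the
across-species SD of FC larger in males than females over these 3 genes";
the package uses a permutation test, its own choice: statistic
$\overline{SD}_M - \overline{SD}_F$ over the gene group, null built by
independently swapping each gene × species (FC_M, FC_F) pair's sex labels,
two-sided $p = (1 + \#\{|T^\ast| \ge |T|\})/(n_{perm}+1)$, deterministic
given the seed, `n_perm` ≥ 99 enforced.

*Top genes.* The universe is the DEGs; the rank key is the largest
absolute per-sex log2FC among significant changes (a large but
non-significant FC cannot drive top status); list size is exactly
$\lceil 0.10\, n_{DEG} \rceil$; ties break by the smaller per-sex adjusted
p, then symbol. Shared top genes appear in ≥ `min_species` (default 3)
lists; novel markers are the shared set minus the key panel.

*Enrichment.* One-sided hypergeometric upper tail by exact pmf summation,
query ⊆ background enforced (an absent query gene is an error, not a silent
drop), sets intersected with the background, genes without any set
annotation dropped from query and background alike, and p-values left
deliberately uncorrected — conservativeness trades against discovery here,
and the per-species tables feed a conservation filter anyway: a pathway is
conserved when enriched (p < 0.05) on one side in ≥ `min_species` species,
labeled FEG-only / MEG-only / both. The external tool behind the original
analyses does not document its statistic; the hypergeometric test is this
package's interpretation.

## 2. The synthetic world

`simulate_dataset()` emulates the structure of real two-stage gonadal
designs: two sexes × two stages, configurable replicates (default 3 per
cell — within the 2–5 range of published designs), ~20,000 genes, and genes
planted in nine classes: MEG and FEG via each of the three mechanisms,
SHARED up/down, and null. Class counts are exact largest-remainder
apportionments of the configured proportions; defaults plant 18% DEGs
(the observed cross-species mean fraction of coding genes changing between
stages), split 8% MEG-type, 8% FEG-type, 2% shared.

* Planted |log2FC| is uniform on `effect_range` (default [1.5, 4]; the
  lower bound sits at the DEG threshold so every planted effect is
  detectable in principle, and boundary effects genuinely exercise the
  threshold). "Both"-mechanism genes draw independent magnitudes for their
  up and down components; SHARED genes get equal deltas in both sexes, so
  the grey-vs-colored boundary is exercised.
* T1 is sex-balanced: all planted change happens between T1 and T2, so sex
  enrichment at T2 arises purely from the planted mechanism.
* Counts are NB with mean $s_j \mu_g 2^{\Delta}$ and dispersion
  $\alpha_g = 0.01 + 0.5/\mu_g$ (a typical bulk RNA-seq mean–dispersion
  relationship); baselines are log-normal (median 100 counts, log-sd 1);
  library sizes are log-uniform in [0.5, 2] so size factors are non-trivial
  in every test. Intensities are Gaussian: baseline N(7, 2) per gene,
  residual sd 0.3 on the log2 scale.
* One seed drives a single generator stream in documented order (gene-level
  quantities, then library sizes, then the matrix), making outputs
  bitwise-reproducible.

**What a green test does not establish.** The generator omits batch
effects, probe cross-hybridization, correlated genes, composition bias
beyond random library sizes, outlier samples, and mean–variance quirks of
real microarrays. Recovery results on this world bound the pipeline's
correctness (labels follow from the drawn deltas by construction; moments
are test-verified against the NB model), not its performance on real data.
In particular the near-perfect planted-class recall reflects strong,
well-separated planted effects, and the all-null calibration reflects
exactly the NB / Gaussian models the engines assume.

## 3. Numerical and interface choices

* Delimiters auto-detect between tab and comma; gene ids are opaque
  strings; sex/stage tokens normalize case-insensitively.
* Intensity matrices are assumed already normalized; no normalization is
  applied to them. Probe-level data stay at probe resolution through DE;
  collapse happens only at cross-species harmonization, keeping DE faithful
  to source resolution.
* The size-factor scale-equivariance property holds for factor *ratios*:
  scaling one column rescales every geometric mean by $c^{1/n}$, so raw
  factors shift by that common constant too.
* NB Wald log2FC invariance to a common count scaling is exact when the
  constant is folded into the size factors and approximate (through the
  re-estimated dispersion) when counts themselves are scaled; it degrades
  at very low counts.
* Degenerate inputs: constant intensity matrices with `d0 = 0` are
  untested; zero mean difference with zero variance is a well-defined null
  (p = 1); empty gene-set collections, empty panels, disjoint gene
  universes and sub-minimal designs are errors, not warnings.
* The CLI consumes JSON configs (keys mirror `simulation_config()` /
  `pipeline_config()`), exits 0/1/2 for ok / validation error / runtime
  error, and makes figures opt-in (`--plots`) so headless runs stay clean.

## 4. Known limitations

* The NB engine's raw p-values are conservative at 2–3 replicates per
  group (the price of the $t$ reference; see §1.1) and the moment
  dispersion estimator is inefficient relative to shrinkage estimators —
  power at small designs is below what DESeq2-style moderation achieves.
* Cook's flagging with the cutoff 19.17 is effectively inert for
  well-behaved data (it needs ~7σ observations); it exists to catch gross
  single-sample corruption.
* The mechanism taxonomy is threshold-dependent: a gene with a true change
  just below the FC threshold in one sex moves between `both` and
  `*-only` categories.
* Cross-species conclusions inherit whatever the ortholog map misses;
  unmapped symbols fall back to uppercase identity, which over-merges
  paralogs with shared names and under-merges true orthologs with
  different names.
* Paired designs, batch correction, and more than two stages or sexes are
  out of scope.
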