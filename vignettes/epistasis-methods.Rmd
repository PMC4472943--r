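---
title: "Quantifying TTP-phosphorylation-mediated DUSP1 effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TTP-phosphorylation-mediated DUSP1 effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episttp)
```

## The scientific question

DUSP1 (MKP-1) is a phosphatase that switches off p38 MAPK and JNK and
thereby limits macrophage inflammatory responses. One of the ways p38
MAPK sustains inflammatory gene expression is by driving MK2-mediated
phosphorylation of tristetraprolin (TTP, encoded by *Zfp36*) at serines
52 and 178, which inactivates this mRNA-destabilizing protein. A
four-genotype factorial experiment — wild type, *Dusp1* knockout, the
phosphosite knock-in *Zfp36aa* (S52A/S178A, constitutively active TTP),
and the double mutant — lets one ask, transcript by transcript, how much
of the effect of deleting *Dusp1* requires phosphorylatable TTP.

`episttp` implements that analysis as a pipeline over a processed
expression matrix: probe filtering, per-probe two-way ANOVA with
Benjamini–Hochberg FDR, induction summaries, profile clustering, the
central DE1/DE2 epistasis statistic with a global regression, mRNA decay
fitting for chase experiments, ΔΔCt quantification, and ARE motif
scanning. A synthetic-data generator with known ground truth makes every
stage testable without any external download.

## The epistasis model

For each LPS-induced transcript, the **DUSP1 effect** is the mean
expression ratio of *Dusp1*-null to *Dusp1*-wild-type macrophages under
LPS, on the log2 scale:

* **DE1** — in the *Zfp36* wild-type background:
  `mean(log2 Dusp1KO) - mean(log2 WT)`;
* **DE2** — in the *Zfp36aa* background:
  `mean(log2 DoubleMut) - mean(log2 Zfp36aa)`.

Computed as a difference of log2 replicate means, each DE equals both
the log2 ratio of the group geometric means and the mean of all pairwise
replicate log-ratios; these identities are asserted in the test suite.

The no-epistasis null is DE1 = DE2: deleting *Dusp1* has the same effect
whether or not TTP can be phosphorylated. Writing a transcript's true
DUSP1 effect as $\delta$ and the fraction of it mediated by TTP
phosphorylation as $\phi$, the generative model used throughout is

$$\mathrm{DE1} = \delta, \qquad \mathrm{DE2} = (1-\phi)\,\delta .$$

Two summaries address the null:

1. **Per transcript**, a test of DE1 = DE2 with significance tiers
   `ns` (p ≥ 0.01), `significant` (p < 0.01) and `highly_significant`
   (p < 0.0001).
2. **Globally**, a through-origin regression of log2 DE2 on log2 DE1.
   The least-squares slope $\hat\beta = \sum xy / \sum x^2$ converges to
   the $\delta^2$-weighted mean of $(1-\phi)$, i.e. the average fraction
   of the DUSP1 effect that survives loss of TTP phosphorylation; the
   diagonal slope 1 is the null. Through-origin is the default because
   the null line passes through the origin; an ordinary free-intercept
   fit is available since nothing forces the fitted line through zero.

## Error models for the per-transcript test

The published procedure estimates the error of each DE from *all
pairwise* replicate ratios: with 3 + 3 replicates, 9 log-ratios per
background, compared by a two-sample Welch t-test. The package
implements this faithfully as the default (`error_model = "pairwise"`).
It should be understood as anti-conservative: the 9 ratios are built
from only 6 numbers, so they are strongly dependent. Analytically, the
sample variance of the ratio set estimates
$\tfrac{3}{4}(s^2_{num}+s^2_{den})$ and the Welch standard error of the
DE1 − DE2 difference understates the true one by a factor of 2; at a
nominal p < 0.01 the realized false-positive rate is roughly 15–20%.

`error_model = "groupwise"` is the calibrated alternative: a t-test on
DE1 − DE2 with variance propagated from the four replicate-group
variances and Welch–Satterthwaite degrees of freedom. Under null
simulations its p < 0.01 rate is below 1%. Use `pairwise` to reproduce
the published procedure, `groupwise` whenever the tier calls are to be
interpreted as calibrated hypothesis tests.

## Regression dilution and the corrected slope

DE1 is itself a noisy quantity (the difference of two 3-replicate
means), and noise in the regressor attenuates a least-squares slope
toward zero: with $m$ transcripts and per-transcript DE1 sampling
variance $v_x$,

$$E[\hat\beta] \approx \beta\,
  \frac{\sum \delta^2}{\sum \delta^2 + m\,v_x}.$$

At realistic replicate noise (log2 SD ≈ 0.2) this bias is ~1–2% — small
for effect estimation, but decisive when *testing* the null slope 1,
because the bias does not shrink with more transcripts while the
standard error does. The naive 95% CI then excludes 1 under the null in
far more than 5% of experiments.

`fit_epistasis_regression(..., x_error_var =)` therefore offers the
method-of-moments errors-in-variables correction
$\hat\beta_c = \sum xy / (\sum x^2 - \sum v_{x,i})$, with $v_{x,i}$
estimated per transcript from the WT and Dusp1KO replicate variances
(`epistasis_analysis(correct_attenuation = TRUE)` wires this up). Its
CI is a seeded case-resampling bootstrap (2000 resamples, percentile
interval); each resample recomputes both the cross-products and the
error-variance sum from the resampled transcripts, so the uncertainty of
the correction itself is propagated. In null simulations at the study
conditions the corrected slope is unbiased and its 95% CI covers 1 at
the nominal rate, while the uncorrected interval does not. The
uncorrected fit remains the default because it is the published
procedure; the corrected mode is the right tool for calibration
questions.

## The synthetic experiment

`simulate_experiment()` emulates the study design: 4 genotypes × 2
treatments × 3 replicate arrays, log2-scale means

| group | log2 mean |
|---|---|
| any genotype, untreated | $\mu$ |
| WT, LPS | $\mu + \lambda$ |
| Dusp1KO, LPS | $\mu + \lambda + \delta$ |
| Zfp36aa, LPS | $\mu + \lambda + \zeta$ |
| DoubleMut, LPS | $\mu + \lambda + \zeta + (1-\phi)\delta$ |

with i.i.d. Gaussian log2 replicate noise and linear intensities
$2^{(\cdot)}$. Noise is therefore log-normal, matching the
multiplicative error structure of array intensities: ratios become
differences with constant variance on the log scale.

Defaults, chosen once as plausible for processed two-color array data
from biological triplicates: baseline $\mu \sim N(8, 2^2)$ (log2 units),
induction $\lambda \sim N(2, 1)$ for 20% of genes, DUSP1 effect
$\delta \sim N(1, 0.5^2)$ for half the induced genes, replicate noise
$\sigma = 0.2$ log2 units, $\zeta = -0.5$ applied to direct TTP targets
in *Zfp36aa* backgrounds. The TTP-mediated fraction $\phi$ is a mixture
of a point mass at 0 and a Beta(2, 2), so fully TTP-dependent,
partially dependent, and independent genes all exist. The untreated
baseline is shared across genotypes because the dysregulation of
interest is LPS-dependent. These are fixtures, not estimates of the real
data: the source study reports no effect-size distributions, so recovery
tests demonstrate correctness of the estimators under a known truth, not
properties of the deposited arrays.

The generator returns the truth table alongside the data, and
`(1-\phi)\delta` is the expected DoubleMut − Zfp36aa contrast *by
construction*, which downstream tests exploit as an oracle.

For clustering tests, `simulate_profiles()` plants four archetypal
relative-expression patterns across the genotype tracks. The archetypes
were chosen with low pairwise profile correlation (≤ 0.30): planted
classes that are nearly collinear in correlation geometry cannot be
separated by *any* correlation-distance method, and a recovery oracle is
only informative about the implementation when the truth is separable.

## Supporting stages: choices that matter

**Filtering.** A probe is kept if at least 2 of 3 replicates *strictly*
exceed linear intensity 100 in LPS-treated WT or Dusp1KO samples
("exceed" read literally), and dropped if in any replicate group the
sample SD (n−1 denominator) exceeds the group mean. The dispersion rule
is applied to every replicate group of the analyzed timepoint — the
conservative reading, removing any probe with one aberrant group.
Datasets from different LPS durations are analyzed separately.

**ANOVA.** The per-probe two-way genotype × treatment ANOVA is the
balanced fixed-effects decomposition, vectorized across probes; pairwise
contrasts use the pooled residual variance with N − (cells) df. The
published analysis names a mixed model without identifying the random
factor (plausibly scan batch, which is unavailable), so fixed effects is
the reproducible choice; this mainly affects attempts to reproduce the
published genome-scale counts, which are benchmark-only. Zero residual
variance flags a probe `untestable` (p = NA, never 0). Fold changes are
ratios of group geometric means, consistent with log-scale modeling; the
significance gate for induction calls is q < 0.05 after BH correction
(`stats::p.adjust`).

**Clustering.** Average-linkage agglomerative clustering on 1 − Pearson
correlation between row-standardized profiles, cut to exactly k clusters
(k = 4 at 1 h, 6 at 4 h in the study's analyses). The original Genesis
settings are unreported, so exact reproduction of published cluster
memberships is a soft target. Zero-variance rows have no defined
correlation and are assigned to the nearest centroid by Euclidean
distance, with a warning.

**Decay.** Chase series (percent of t = 0 after reference-gene and t0
normalization) are fitted by unweighted OLS of ln(value) on time —
appropriate under multiplicative error — giving k, t½ = ln 2 / k, the
regression SE of k and R². A bounded-plateau model
$y = p + (100-p)e^{-kt}$ (Levenberg–Marquardt, p ∈ [0, 100)) is
available behind a flag; it is unstable on the 4–6 point series typical
of chases, hence not the default. Fitted k within numerical tolerance of
zero (≤ 1e-10) reports "no measurable decay" with infinite half-life.
Half-life comparisons test the difference in k by a z statistic, because
k is the directly fitted, approximately Gaussian parameter. Simulated
chases apply log-normal noise to every timepoint including t = 0,
emulating measurement error in the normalized ratio.

**Motif scanning.** The consensus TTP site is the heptamer UAUUUAU;
overlapping occurrences are counted (the functional nonamer UUAUUUAUU is
two overlapping heptamers, and AREs cluster), scanning is single-strand
mRNA-sense, T/U are equivalent, and N never matches. Positions are
1-based, the R/Bioconductor convention. The stricter nonamer is
available via the `motif` argument.

## Problem sizes and what the tests show

The validation suite runs entirely on synthetic data at the study's
design scale: 600 transcripts × 4 genotypes × 2 treatments × 3
replicates for the epistasis properties (20 seeded runs per property),
1000 random vectors/sequences for the exact BH and motif equivalences,
and 20-seed grids for decay recovery. These sizes keep the full suite
within a few minutes on one core while leaving Monte Carlo error well
below the asserted tolerances.

Passing tests demonstrate that the estimators recover a known generative
truth under log-normal replicate noise and a balanced design. They do
not certify behavior on real arrays — probe-level artifacts, spatial
trends, unbalanced designs after sample failures, and correlated
biological replicates are all outside the generator — and the published
genome-scale counts (which depend on the deposited data and on
unreported mixed-model details) are treated as optional benchmarks, not
acceptance conditions.

## Known limitations

* The pairwise error model reproduces the published procedure but is
  anti-conservative by construction; tier counts under it overstate
  per-transcript significance (see above for the calibrated
  alternative).
* The naive through-origin slope carries a small attenuation bias; use
  `correct_attenuation = TRUE` when testing slope = 1.
* The ANOVA is fixed-effects and requires a balanced design; unbalanced
  inputs are rejected rather than approximated.
* ΔΔCt assumes perfect (2-fold per cycle) amplification efficiency.
* The plateau decay model needs late timepoints to identify p; on short
  chases it can trade off p against k.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_params(n_genes = 600, frac_induced = 1,
                                      frac_dusp1_responsive = 1,
                                      ttp_zero_prob = 0,
                                      ttp_beta_shape1 = 4.5,
                                      ttp_beta_shape2 = 5.5, seed = 1))
lg <- log2_transform(sim$expression, pseudocount = 0)
res <- epistasis_analysis(lg, sim$design)
print(res)
plot(res)   # DE2 vs DE1, null diagonal and fitted line
```
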