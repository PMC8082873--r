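---
title: "Validating microbiome measurements against mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating microbiome measurements against mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockval)
```

## The measurement problem

Shotgun metagenomics measures the *composition* of a microbial community:
the relative abundances of its taxa, constrained to sum to a constant.
Every step of the workflow — cell lysis, DNA extraction, library
construction, PCR, sequencing, profiling — can distort those relative
abundances, and the only way to quantify the distortion is to measure a
**mock community** whose composition is known in advance (the "ground
truth"): either an equimolar pool of genomic DNA from a defined set of
strains, or a defined mixture of whole cells.

`mockval` implements the quantitative side of such a validation study. It
covers four questions:

1. **Accuracy / trueness** — how close are measured compositions to the
   ground truth, and do they meet best-practice targets?
2. **Precision** — how variable are replicated measurements, at the level
   of repeatability (same everything), intermediate precision (operator
   or reagent lot varied within a laboratory), and interlaboratory
   reproducibility (per ISO 5725)?
3. **Bias mechanisms** — how strongly does genomic GC content distort
   abundances, and how non-random is DNA fragmentation?
4. **Detection limits** — below which relative abundance does a taxon
   stop being reliably detected (LOD) or reliably quantified (LOQ)?

## Compositional geometry

Relative abundances live on the simplex, so all dispersion and distance
calculations use Aitchison geometry. A composition
$x = [x_1, \dots, x_D]$ is closed to a constant $\kappa$ (1 for
fractions, 100 for percent); the package works internally with
$\kappa = 1$ and treats percent as an I/O convention, detected from row
sums. The centred log-ratio transform
$\mathrm{clr}(x)_i = \ln(x_i / g(x))$, with $g(x)$ the geometric mean of
the parts, maps compositions to a zero-sum Euclidean space where:

* the **compositional mean** of a set of measurements is the closed
  geometric mean (the clr image of the mean of clr vectors);
* the **Aitchison distance** $d_A(x, y)$ is the Euclidean distance of
  clr vectors, equal to the normalised pairwise-logratio form
  $\sqrt{\tfrac{1}{2D}\sum_{i,j} [\ln(x_i/x_j) - \ln(y_i/y_j)]^2}$;
* the **metric variance** of a set is $\tfrac{1}{2D}$ times the sum of
  all pairwise log-ratio variances (the *variation matrix*), equal to the
  sum of clr-coordinate variances.

These identities are not just documentation: the test suite asserts both
routes against each other on randomly generated data, and the
distance-based ANOVA below relies on them.

Zeros are incompatible with log-ratios. Observed zeros (taxa below the
detection limit at a given depth) are replaced by a small floor — 0.001%
by default — and the row is re-closed. Sample variances use the $n-1$
denominator throughout.

## Agreement metrics

Compositional distances are correct but hard to communicate. The package
therefore reports agreement with the ground truth primarily as the
**geometric mean of taxon-wise absolute fold-differences**:

$$\mathrm{gmAFD}(x, y) = \Big(\prod_{i=1}^{D} e^{\left|\ln(x_i / y_i)\right|}\Big)^{1/D}$$

together with the maximum taxon-wise fold-difference. A gmAFD of 1.15
reads directly as "measured abundances are off by 15% on average".
**Trueness** is the gmAFD of the compositional mean of replicates to the
truth; **accuracy** is the gmAFD of an individual measurement.

Shipped best-practice targets (`threshold_config()`): gmAFD $\le$ 1.15
and maximum AFD $\le$ 1.5 for a DNA mock community, gmAFD $\le$ 1.55 and
maximum AFD $\le$ 3.1 for a cell mock community, where ground-truth
assignment itself is harder. A value exactly at the bound passes, since
the bounds are stated as achievable targets.

Precision is reported as the **quadratic mean of taxon-wise coefficients
of variation** (qmCV, in percent), computed directly from replicate
tables and, equivalently for small dispersion, from the metric variance
as $100\sqrt{\mathrm{mvar}/D}$. The proportionality is a small-variance
approximation derived for near-even compositions: for strongly skewed
compositions the closure term in the CV of dominant taxa breaks it, which
is why the equivalence tests simulate near-even communities (the regime
mock communities are designed for).

## Distance-based random-effects ANOVA

Intermediate precision and interlaboratory reproducibility are estimated
with a one-way random-effects ANOVA on squared Aitchison distances. With
$p$ groups of $n$ replicates,

$$TSS_b = n \sum_{i=1}^{p} d_A^2(\mathrm{cen}(X_i), \mathrm{cen}(X)), \qquad
  TSS_w = \sum_{i,j} d_A^2(x_{ij}, \mathrm{cen}(X_i)),$$

after which everything follows standard ANOVA: $MS_w$ is the
within-group metric-variance component and $(MS_b - MS_w)/n$ the
between-group component, truncated at zero (and flagged) when the raw
estimate is negative, as is standard for random-effects models.
Components are converted to qmCVs by the proportionality above, using
the number of taxa in the analysed table as $D$.

Design choices worth stating:

* The grand centre is the closed geometric mean of *all* measurements,
  which coincides with the centre of group centres under balance; the
  supported designs are balanced, with an explicit harmonic-mean option
  for unbalanced data.
* One-sided 95% upper confidence bounds use an exact chi-square bound on
  $p(n-1)$ degrees of freedom for the within component and a
  Satterthwaite-approximated chi-square bound for the total
  $(MS_b + (n-1)MS_w)/n$. Exact interval construction for random-effects
  composites is not settled methodology, so the construction is isolated
  behind `upper_confidence_bound()` and results that depend on bound
  width should be treated as approximate.
* No multi-factor or nested decomposition is offered; multiple nuisance
  factors should be combined into a single grouping factor before
  analysis. Permutation tests are out of scope — the decomposition is
  used for variance components, not hypothesis testing.
* An optional outlier heuristic (flagging a replicate whose within-group
  distance exceeds three times the median pairwise distance) was
  considered and deliberately left out of the automated workflow;
  `pairwise_distance_summary()` exports the raw distances so such rules
  can be applied transparently by the analyst.

## Bias summaries

**GC bias.** For every unordered pair of strains, the log2 abundance
ratio is regressed on the pairwise difference in genomic GC content with
an intercept-free linear model; the slope (log2-fold per percentage
point) is the bias summary, also reported as $2^{10\,\text{slope}}$-fold
per 10% GC difference. Unordered pairs suffice: the ordered duplicates
are antisymmetric in both response and covariate and provably leave the
slope unchanged (asserted in the tests).

**Fragmentation bias.** Non-random fragmentation leaves a signature in
the base composition of early read cycles. The statistic is the
Aitchison distance between observed and expected (A, C, G, T)
frequencies per position, averaged over the first 15 forward-read cycles
by default. Zero base frequencies — which occur only in degenerate
inputs — are floored at $10^{-6}$ before the log-ratio transform.

## Detection limits

`summarize_detection()` reduces a replicate table to per-taxon
(mean abundance, detected count, total, CV) records, with zeros included
in means and CVs and CVs left uncapped — a taxon missing from some
replicates has an inflated CV, which is exactly the signal the LOQ
regression exploits.

**LOD.** Binomial regression of detection outcomes on log mean abundance
with a complementary log-log link; the LOD is the abundance where the
fitted probability of detection reaches 0.95. The fit weights each taxon
by its replicate count by default (an unweighted quasibinomial mode is
provided, since either reading of "binomial regression of species-wise
PODs" is defensible); it refuses data with no undetected outcomes and
requires a positive slope.

**LOQ.** The CV-versus-abundance relation is fitted with the negative
exponential $CV(m) = c_0 + a\,m^{-b}$, $a, b > 0$, concretising the
classic decay-to-plateau form; the lower plateau $c_0$ is fixed at the
mean CV of the top 10% most abundant taxa
($\lceil 0.1 N \rceil$, minimum 1, abundance ties broken by taxon
label). The LOQ solves $CV(m) = 0.40$:
$\mathrm{LOQ} = (a / (0.40 - c_0))^{1/b}$, undefined when the plateau
already exceeds the threshold. The `nls` fit starts from $b = 0.5$ and
$a$ set from the median of $(CV - c_0)\sqrt{m}$ over points above the
plateau — fixed values, so fits are reproducible. Both limits are
equivariant under a common rescaling of abundances (percent versus
fraction), and both are functions of sequencing depth and profiler;
depth normalisation is deliberately the caller's responsibility.

## What the synthetic-data generator does and does not emulate

`make_ground_truth()` encodes the reference design: 20 strains, even
(equimolar) expected abundances, genomic GC contents spanning
31.5–62.3%, alternating Gram types, genome sizes 2–6 Mbp.
`simulate_measurement()` distorts the truth on the log scale —

$$\ln a_i = \ln e_i + \ln(2)\,\beta_{GC}\,(GC_i - \overline{GC})
  - \pi\,[\text{Gram}^+_i] + u_i + \varepsilon_i,$$

with $u_i$ a per-group random effect shared by replicates
(`simulate_hierarchy()` draws one vector per group,
$u_i \sim N(0, \sigma_b^2)$), $\varepsilon_i \sim N(0, \sigma_w^2)$
independent per measurement, followed by closure and, optionally,
multinomial count sampling at a chosen depth. Additive log-scale effects
before closure are the natural counterpart of the log-linear GC-bias
summary and the multiplicative agreement metrics. All generators are
pure functions of (parameters, seed).

Under this model the clr-scale covariance is exactly the one-way
random-effects structure the ANOVA assumes, with per-component metric
variances $\sigma^2(D-1)$ — the identity the recovery tests use. What
the generator does **not** emulate: cross-taxon correlation of group
effects, read-level artefacts (sequencing error, duplicates, fragment
length), profiler-specific misassignment, and the wet-lab calibration
chain by which real cell-mock ground truths are assigned. Passing
recovery tests therefore demonstrates estimator correctness under the
assumed noise structure, not robustness to every artefact of real
sequencing data.

Default problem sizes in the tests and the reproduction script — 200
simulated studies of $p = 10$ groups $\times$ $n = 2$ replicates for
component recovery, 200 taxa $\times$ 50 replicates for the LOD, 100
taxa for the LOQ, 100 replicate sets for the proportionality check —
were chosen so Monte-Carlo error is comfortably below the assertion
tolerances while a full run stays interactive.

## Degenerate inputs and numerical conventions

* Closure refuses zeros (pointing to `replace_zeros()`) and negative or
  zero-sum input.
* Label alignment is always explicit: distance and fold-difference
  functions error on mismatched taxon sets; `align_taxa()` intersects
  and re-closes when the caller asks for it.
* Percent/fraction ambiguity is resolved by row sums (near 100 versus
  near 1); anything else errors rather than guessing.
* PCA component signs are fixed (largest-magnitude loading positive) so
  ordinations are deterministic across platforms.
* The cross-protocol abundance filter keeps taxa at or above 0.05% mean
  abundance in *either* profile, then re-closes; with filtered fecal
  data the filter is applied before zero replacement by default, and
  both orders are available by composing `abundance_filter_union()` and
  `replace_zeros()` explicitly.
* All-identical data yield zero sums of squares and collapse the
  confidence bounds to zero instead of producing NaN degrees of freedom.

## A worked run

```{r example, eval = FALSE}
truth <- make_ground_truth(D = 20)
model <- measurement_model(gc_slope = -0.01, sigma_within = 0.05,
                           sigma_between = 0.10)
study <- simulate_hierarchy(truth, model, p = 10, n = 2, seed = 1)

report <- run_validation(study$abundance, truth,
                         config = threshold_config("dna_mock"))
report
glance(report$accuracy)
vd <- decompose_variance(study$abundance, study$metadata, "group")
tidy(vd)
```

## Limitations

The best-practice thresholds shipped here were derived for specific
reference materials and are not automatically transferable to other mock
communities. The qmCV–metric-variance conversion is a small-dispersion,
near-even approximation. Confidence-bound coverage rests on normality of
clr-scale effects. Detection limits depend on sequencing depth and the
profiling tool, and should be re-estimated per pipeline configuration.
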