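---
title: "Modelling soil bacterial pH responses with HOF curves"
author: "ecohof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil bacterial pH responses with HOF curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecohof)
```

Soil pH is the strongest single predictor of soil bacterial community
composition at landscape scale. `ecohof` turns that observation into per-taxon
ecology: it fits each OTU's read counts along a pH gradient with a small
hierarchy of response shapes, selects a shape, extracts the pH at which the
taxon is most abundant, and assigns the taxon to a pH preference group. Around
the fitting core sit the tools needed to use such a trait table: count-table
filtering, match criteria for transferring traits to new studies, indicator
analysis, accumulation curves, and prediction of a new study's community
structure from nothing but its soil pH.

## The response model

All five shapes are built from the decreasing logistic
$g(t) = 1/(1 + e^{t})$ on a scaled gradient
$x = (\mathrm{pH} - \mathrm{pH}_{\min}) / (\mathrm{pH}_{\max} -
\mathrm{pH}_{\min}) \in [0, 1]$:

| type | formula | shape | free parameters |
|------|-------------------------------|--------------------------|---|
| I    | $\mu = M\,g(a)$               | flat                     | 1 |
| II   | $\mu = M\,g(a+bx)$            | monotone                 | 2 |
| III  | $\mu = M\,g(a+bx)\,g(c)$      | monotone with plateau    | 3 |
| IV   | $\mu = M\,g(a+bx)\,g(c-bx)$   | symmetric unimodal       | 3 |
| V    | $\mu = M\,g(a+bx)\,g(c-dx)$   | skewed unimodal          | 4 |

$M$ is not a free parameter: it is fixed at the OTU's maximum observed count,
so the products above always satisfy $0 \le \mu \le M$ and AIC values are
comparable across shapes. Raw read counts are modelled with a Poisson
likelihood; no depth offset is applied by default, matching the convention of
presenting per-OTU fits on the raw read scale. The shapes are nested
(I $\subset$ II $\subset$ III, IV $\subset$ V), which the optimizer exploits
and the test suite asserts.

Slopes are constrained to $b, d \in [0, 200]$ and intercept-like terms to
$a, c \in [-50, 50]$. Increasing responses are reached not by negative slopes
but by also fitting every shape on the reversed gradient $1 - x$ and keeping
the better likelihood; this removes a sign ambiguity that otherwise lets the
optimizer wander between equivalent parameterizations.

## Fitting and model selection

`fit_single_model()` minimizes the Poisson negative log-likelihood with a
bounded quasi-Newton optimizer (analytic gradients, at most 500 iterations)
from a deterministic multi-start set: a $3\times3$ grid of $(a, b)$ values
around a logit-linear regression of the scaled counts, spread starts for $c$
and $d$, and data-informed starts that place a unimodal optimum at the
empirical abundance peak or a plateau at the empirical saturation level.
`hof_fit()` fits the shapes in nesting order and seeds every shape with the
solution of the shape it nests, so the attained log-likelihoods are
non-decreasing along the hierarchy by construction, not by luck.

Selection follows the two-stage rule used in landscape-survey practice: the
shape with the lowest AIC ($2k - 2\log L$, with $k$ the number of free
parameters among $a$–$d$) is chosen initially; the data pairs are then
resampled with replacement 100 times, all shapes refitted on each resample
(warm-started from the original solutions), and the AIC-best shape recorded.
If the modal bootstrap choice differs from the initial choice, the mode wins.
Ties — in AIC and in the bootstrap tally — go to the shape with fewer
parameters. Resamples on which every shape fails to fit are excluded from the
tally and counted in `n_boot_failed`.

Bootstrap refits keep the original $M$ and gradient range fixed so that all
resamples of one OTU are scored on the same scale; refits are warm-started
from the original per-shape optima rather than re-running the full multi-start
grid, which keeps a 200-OTU cohort with 100 resamples each within a few
minutes on one core without changing the selected shapes in practice.

## Optima and pH response groups

* Type I has no optimum and yields the class `no_preference`.
* Type II's optimum is the gradient endpoint with the higher response.
* Types IV and V are maximized on a fine grid (step $10^{-3}$ in $x$,
  locally refined), with the type IV closed form $x^* = (c - a)/(2b)$ used as
  a test oracle.
* Type III plateaus: the two reported optima bound the region where the
  fitted response is at least 0.95 of its maximum. The plateau-edge fraction
  is a documented choice — the convention the trait tables in this field
  follow does not pin it down.

Optima below pH 5.2 give `acid`, above 7.0 `neutral`, between them `mid`;
plateau fits whose two optima straddle a threshold get range classes
(`acid_to_mid`, `mid_to_neutral`, `acid_to_neutral`). The thresholds are
strict inequalities on both sides, so an optimum exactly at 5.2 or 7.0 is
formally unassigned by the label definitions; such values are placed in the
closed middle band (`mid`), a convention applied identically when samples are
banded for indicator analysis. Type II optima sit at the gradient endpoints
and are classified with the same thresholds.

```{r example, eval = FALSE}
ph <- runif(300, 3.63, 8.75)
mu <- hof_response(scale_gradient(ph, 3.63, 8.75), "IV",
                   c(a = -6, b = 14, c = 6), M = 120)
fit <- hof_fit(rpois(300, mu), ph, n_boot = 100, seed = 1,
               gradient_range = c(3.63, 8.75))
summary(fit)
plot(fit)
classify_response(fit$optima_pH)
```

## The synthetic gradient generator

Every downstream stage is testable without survey downloads because
`generate_gradient()`, `generate_truths()`, `generate_community()` and
`generate_study_pair()` produce communities with known answers:

* pH uniform on [3.63, 8.75] (the survey gradient); nominal depths log-normal
  (median 10,000 reads, $\sigma = 0.5$, truncated at 1,000) — a realistic
  spread around the common per-sample filter of 5,000 reads; habitats drawn
  from eight aggregate vegetation classes.
* Truth parameters from broad priors ($a, c \sim U(-10, 5)$;
  $b, d \sim U(2, 60)$; $M$ log-uniform on [5, 500]), stratified over the five
  shapes and, by rejection sampling, over the attainable response classes, so
  recovery confusion matrices have support everywhere. The strong-signal
  cohort used for recovery experiments floors $b, d$ at 10 and $M$ at 50.
  Truths whose expected occupancy along the gradient falls below 15% are
  redrawn: a taxon effectively invisible to a prevalence filter cannot carry
  information about recovery.
* Counts are independent Poisson draws around the truth response — exactly the
  error model the fitting assumes.
* Study pairs share a configurable fraction of truths between a reference and
  a query study, with sharing probability increasing with abundance rank, and
  emit synthetic 12-column match records placing shared OTUs at 97–100%
  identity ($e$-value $10^{-50}$) and novel OTUs at 80–96.9%.

What the generator deliberately does not emulate: overdispersion relative to
Poisson, correlated taxa, spatial or habitat structure in pH, compositional
coupling between rows, chimeras and other artifacts of amplicon processing,
and sequence-level variation (matches are simulated at the record level). A
pass on synthetic data therefore demonstrates the machinery is correct under
its own assumptions, not that real soil data meet those assumptions.

## Matching, indicators, accumulation, prediction

Hit criteria are inclusive: a query OTU counts as matched when some record has
identity $\ge 97\%$ and $e$-value $\le 0.001$; the best hit per query is the
highest bitscore, with ties broken by lower $e$-value and then subject id, so
results do not depend on input row order. Coverage by rarity follows the
rank-bin construction: queries sorted by decreasing total abundance are split
into near-equal contiguous bins (earlier bins take any remainder, a detail the
binning description leaves open) and per-bin match proportions reported.

Indicator analysis uses the group-equalized indicator value:
$A_{ig}$ is the group mean of within-sample relative abundance, normalized
across groups, $B_{ig}$ the occupancy fraction, and
$\mathrm{IndVal} = 100\,A\,B$, with significance from permuting group labels
($p = (1 + \#\{ \mathrm{perm} \ge \mathrm{obs} \}) / (1 + n_\mathrm{perm})$).
Equalized group weights matter because pH bands are never balanced in surveys.
The significance rule (default $p \le 0.05$, 999 permutations) is a documented
choice; published indicator counts depend on it, so exact counts are not
expected to transfer.

Accumulation curves use the permutation estimator (mean and SD of cumulative
richness over random sample orderings) rather than the analytic rarefaction
formula, matching the "random permutations" description; the analytic formula
serves as a cross-check oracle in the tests, and exhaustive enumeration is
available for tables of up to 8 samples.

Community prediction evaluates each matched reference fit at the query
samples' pH and divides by the reference median depth to reach a relative
scale; the matrix is compared to the observed community by NMDS (Bray–Curtis
dissimilarities on per-sample normalized abundances, $k = 2$, Kruskal
stress-1 via monotone regression, best of 20 seeded random starts) and the
squared Pearson correlation of first-axis scores after reflection alignment.
The dissimilarity metric, dimensionality and normalization are documented
assumptions — ordination conventions in this field, not pinned by the
procedure being reproduced. The "100 matched dominant OTUs" are rank-then-
match: rank all query OTUs by total count, keep the most abundant 100 that
have best hits.

## Reproducibility and problem sizes

Every stochastic operation takes a seed; `run_pipeline()` derives a separate
seed per stage from the single config seed, so toggling one stage never
changes another's output, and reruns are byte-identical. Table-level fitting
derives one seed per OTU id, so fitting a subset reproduces the full run's
rows.

The validation experiments shipped with the package use 200 OTUs × 500
samples for recovery, 200 random OTUs × 150 samples for the nesting property,
and a 150-reference / 200-query pair with 300 samples per study for the
end-to-end prediction analogue; these sizes give stable statistics while
keeping a full run in minutes on one core.

## Known limitations

* Adjacent HOF shapes are weakly identifiable. Because $M$ is fixed at the
  maximum observed count — which Poisson noise inflates above the true curve
  maximum — a monotone response that saturates inside the gradient is fitted
  better by the plateau shape (III) than by II, and the single extra
  parameter separating IV from V is within AIC noise for many unimodal taxa.
  Shape labels should be read as families (flat / monotone-plateau /
  unimodal), while the pH optima, which drive everything downstream, are
  robust to flips between adjacent labels.
* Poisson error understates the variance of real amplicon counts; an
  overdispersed error model would widen bootstrap tallies.
* Optima are only identified within the sampled gradient: a taxon whose true
  optimum lies outside [3.63, 8.75] is reported at the boundary.
* `nll`-scale comparisons assume a shared $M$ per OTU; comparisons across
  OTUs should use classes and optima, not likelihoods.
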