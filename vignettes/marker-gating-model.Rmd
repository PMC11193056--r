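---
title: "Probabilistic marker gating for multiplexed immunofluorescence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic marker gating for multiplexed immunofluorescence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifGate)
```

## The problem

Multiplexed immunofluorescence (mIF) produces, after segmentation and
quantification, a table with one row per cell and one intensity per marker
channel. Phenotyping starts from *marker gating*: deciding, per channel,
which cells are marker-positive. Manual thresholding is subjective and
slide-specific; fully automatic clustering is hard to audit and unstable
across batches, because slide-to-slide variation changes not only the
location and scale of the marker intensity distribution but its shape.

mifGate takes the semi-automated middle road: a parsimonious probability
model is fitted independently to each (slide, channel) stratum, the user
supplies biologically motivated *constraints* that keep several hundred
independent fits mutually consistent, and the output is a per-cell
*probability* of marker positivity rather than a hard call.

## The model

Normalized intensities are nonnegative with a genuine point mass at zero
(an artifact of autofluorescence adjustment). Each stratum is modeled as a
zero-inflated two-component gamma mixture

$$P(X = x) \;=\; I(x = 0)\,\lambda_0 \;+\;
  I(x > 0)\sum_{k=1}^{2} \lambda_k f(x; a_k, b_k),$$

where $f(\cdot; a, b)$ is the gamma density with shape $a$ and scale $b$,
$\lambda_0$ is the zero proportion, and components are ordered by their
modes $m_k = (a_k - 1) b_k$: the lower-mode component holds
marker-negative cells, the higher-mode component marker-positive cells
($m_2 > m_1$). The gamma family fits the strictly positive, skewed
densities seen across mIF channels well, and its mode is an interpretable
anchor for constraints.

Two probabilities are reported per cell:

* the **posterior** $P(Z = 2 \mid X = x) =
  \lambda_2 f(x; a_2, b_2) \big/ \sum_k \lambda_k f(x; a_k, b_k)$ for
  $x > 0$ and $0$ at $x = 0$;
* the **marginal** $P(X \le x \mid Z = 2) = F(x; a_2, b_2)$, the positive
  component's CDF.

The printed form of the posterior in some descriptions of this model omits
the mixing proportions $\lambda_k$. We default to the $\lambda$-weighted
Bayes form above because it is the quantity whose per-cell average is a
consistent estimator of $\lambda_2$ (which `meanPosteriorProportion()`
exploits); `posteriorProb(..., weighted = FALSE)` gives the unweighted
ratio $f_2/(f_1+f_2)$ for users who want the other convention.

### Monotonicity correction

When the negative component has the heavier right tail, the raw posterior
rises and then *falls* with intensity — an artifact no one gating cells
wants. `monotoneAdjust()` finds the first grid point $x^*$ where the
(weighted) positive-component curve reaches the negative one (ties count
as crossing) and, beyond $x^*$, replaces the negative curve by its running
minimum and the positive curve by its running maximum. The corrected
posterior is unchanged before $x^*$ and nondecreasing after it. The grid
is the sorted unique observed positive values of the stratum — the
adjustment is defined exactly where cells live — and off-grid queries are
interpolated piecewise-linearly, clamped to the grid ends.

## Closed-form estimation

Classical gamma-mixture EM needs an inner numerical optimization in every
M-step, which does not scale to hundreds of strata with $10^4$–$10^6$
cells. Instead the M-step uses a closed-form weighted estimator derived
through the generalized gamma family (Stacy form,
$f \propto \gamma x^{a\gamma-1}e^{-(x/b)^\gamma}$): differentiating the
expected log-likelihood with respect to scale and exponent, solving, and
setting $\gamma = 1$ yields, with $W = \sum w_i$, $S_1 = \sum w_i x_i$,
$S_L = \sum w_i \ln x_i$, $S_{XL} = \sum w_i x_i \ln x_i$ and
$D = W S_{XL} - S_L S_1$:

$$\hat a = \frac{W S_1}{D}, \qquad \hat b = \frac{D}{W^2}.$$

$D > 0$ for any weighted sample with at least two distinct values
(Chebyshev's sum inequality), so the estimator always exists away from
degeneracy. It is not the gamma MLE, but approaches it in large samples;
the test suite verifies agreement within 0.5% of an independently
root-found MLE at $n = 10^5$ for shapes 0.5–30.

### Mode constraints

Users constrain each component's mode to an interval $(l_k, u_k)$, either
fixed or as quantiles of the stratum's intensity distribution. Because the
expected log-likelihood is concave in $(a, b)$, a violated constraint puts
the optimum on the boundary line $(a-1)b = \text{bound}$;
`constrainedMStep()` maximizes along that line by bracketed 1-D search
over $\log(a - 1)$ (bracket $a \in (1 + 10^{-6}, 10^3)$, tolerance
$10^{-8}$), which a grid-search oracle confirms to within $10^{-4}$
log-likelihood units in the tests.

Quantile constraints are resolved once, before the first E-step. When
fitting through `fitMarker()`/`fitBatch()` they resolve against **all**
cell values of the stratum, zeros included, so a lower bound at
probability $1 - p$ means "a fraction $p$ of cells lies above the bound" —
the natural reading when $p$ is an expressed-cell fraction. A resolved
bound can additionally be ceilinged (`cap`) or deliberately shifted up
(`inflate`); the latter implements the "inaccurate" simulation scenario.

### EM details and failure handling

* **Initialization** is deterministic, so refits are bit-identical and
  permutation invariant: values are split at the 80th percentile and each
  block seeds a component via the closed-form estimator. When the positive
  component carries a finite lower mode bound, a second start splitting at
  that bound is also run and the higher final log-likelihood wins. The
  second start matters for rare populations: at an expressed fraction of
  $10^{-3}$ the 80th-percentile split seeds the positive component inside
  the negative bulk, and EM can stall in a local optimum in which the
  positive component models the negative tail.
* **Convergence**: relative log-likelihood change below $10^{-6}$, at most
  500 iterations.
* **Monotone safeguard**: the closed-form update approximates the exact
  M-step maximizer, so on its own it can occasionally *lower* the
  likelihood. Each iteration therefore accepts the component update only
  if the observed log-likelihood does not decrease, otherwise applying
  just the mixing-proportion update (which always ascends). Traces are
  nondecreasing by construction, and the closed-form speed is retained
  because the fallback is rare.
* **Failure is data**: non-finite likelihood, a mixing proportion below
  $10^{-4}$ (component collapse), a persistent mode tie (after one
  $+10^{-6}$ scale perturbation), or iteration exhaustion mark the fit
  nonconverged rather than raising. Batch runs report these strata
  (`convergenceReport()`), their probabilities propagate as `NA`, and
  downstream summaries exclude them explicitly — mirroring how slides that
  fail to fit are discarded and reported in practice.
* At least 100 positive values (2 distinct) are required to attempt a fit;
  below that the stratum is flagged unfit.

## The fit–diagnose–refit loop

`fitBatch()` fits every (slide, channel) stratum independently — results
do not depend on execution order, and deleting a slide never changes
another slide's fit. `qcSummary()` returns the table behind the
mode-versus-proportion diagnostic scatter (one point per slide; outliers
are slides whose positive mode or positive fraction disagrees with the
rest), `mixtureDensity()` supports density-over-histogram overlays, and
`compareFits()` aligns two fits of the same stratum under different
constraints so a refit can be compared against its predecessor before
being accepted.

## Normalization

`normalizeMeanLog10()` implements slide-level mean division followed by a
log10 transform. Because the model carries an exact point mass at zero,
the default is $\log_{10}(1 + x/\bar x)$, which maps zero to exactly zero
(feeding $\lambda_0$), is monotone, and keeps outputs nonnegative. The
pseudo-count-free convention $\log_{10}(x/\bar x)$ with zeros passed
through is available via `offset = FALSE`; it can produce negative values
for sub-mean intensities, in which case the gamma model applies only after
the user shifts or truncates. The offset convention is the default
precisely because it needs no such handling.

## Synthetic data: what it emulates and what it does not

`simulateSlides()` reproduces a batch-effect study design: the expressed
fraction $p$ is held fixed across slides while everything else — zero
proportion and all four gamma parameters — varies from slide to slide. Per
slide, a parameter set is drawn with replacement from a library, the
proportions are rescaled as
$(\lambda_0', \lambda_1') = (1-p)\,(\lambda_0, \lambda_1)/(\lambda_0 +
\lambda_1)$ with $\lambda_2' = p$, labels are drawn multinomially and
intensities from the matching gamma. Ground truth labels ride along in
`colData(.)$truth`; seeds are split per slide so growing the batch never
reshuffles earlier slides.

The packaged 16-entry library (`defaultParamLibrary()`) stands in for
fitted parameters from real slides, which this package cannot ship; users
with data should build a library from their own fits via
`libraryFromFits()`. The packaged values were fixed under two rules: (i) realistic ranges
on the normalized scale (negative modes 0.04–0.16 with shapes 3.5–7,
expressed modes 0.55–0.95, zero proportions 0.05–0.40, spanning
well-separated to overlapping regimes); and (ii) an analytic
identifiability rule — each entry's $1-p$ elbow must stay below 95% of its
expressed mode down to $p = 0.001$ — because a library entry violating it
makes the rare-population design unrecoverable for *any* method: the
negative tail then outweighs the entire expressed population above every
admissible bound. Early drafts with heavier negative tails (shapes
1.5–3.5) violated the rule for most entries and were revised against the
rule itself, not against fit outcomes.

What the simulation does **not** emulate: spatial structure (no
coordinates), correlation between channels, segmentation errors, and
non-gamma intensity artifacts. Passing recovery tests on these synthetic
slides therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not performance on real images.

### Constraint scenarios

`scenarioConstraints()` builds the three study arms: **accurate** — a
quantile lower bound at $1 - p$ on the positive mode, resolved per slide
(the bound lands at the lower edge of the expressed mass, so the expressed
proportion is recovered essentially unbiased; measured mean estimates in
the acceptance run are within three Monte-Carlo standard errors of the
generating 0.05 and 0.001); **inaccurate** — the same elbow inflated 1.5×,
which lands above the true expressed mode for most library entries;
**none** — unbounded. The qualitative ordering verified in the acceptance
suite is accurate ≥ none ≥ inaccurate in phenotyping accuracy (ARI
against simulation truth) at the 0.05 fraction; at the 0.001 fraction the
unconstrained arm degrades most (it absorbs the negative tail into the
positive component, inflating the estimated proportion by two orders of
magnitude), which is precisely the failure mode the constraints exist to
prevent. One caveat worth stating: with the boundary-exact M-step, the
dual initialization and the monotone safeguard, badly placed bounds in
these synthetic conditions degrade accuracy but do not break convergence
outright — fits settle on the boundary instead of failing, so
convergence-failure counts under inaccurate constraints are not
reproduced here (the corresponding acceptance check documents this as an
expected failure).

## Downstream summaries

* **Soft proportions**: `meanPosteriorProportion()` averages posteriors
  over the cells of a region instead of counting thresholded cells; with
  the weighted posterior this estimates the marker-positive proportion.
* **Spatial interaction**: `ripleyK()`/`ripleyH()` implement Ripley's
  $K$, $L = \sqrt{K/\pi}$ and $H = L - r$ for one point type or a type
  pair on rectangular windows. $H \approx 0$ under complete spatial
  randomness, positive under attraction, negative under repulsion;
  `meanH()` averages the curve over radii for a per-slide scalar. The
  default edge correction is the translation correction — exactly
  symmetric between types and testable against brute-force pair counting
  (`correction = "none"` is that brute-force estimator; `"border"` is
  minus-sampling). The window defaults to the points' bounding box; pass
  the true region geometry when known. The default radius grid is 50
  evenly spaced radii up to the requested maximum; radii beyond half the
  shorter window side are dropped with a warning.
* **Evaluation**: `thresholdPositive()` (ties positive at the threshold,
  default 0.5; missing probabilities give missing calls),
  `assemblePhenotypes()` (first matching definition wins, `"other"`
  fallback), `adjustedRandIndex()` (Hubert–Arabie, listwise NA drop), and
  `simulationReport()` (per-slide bias and ARI against simulation truth,
  nonconverged fits counted and excluded from means). Simulation ARI uses
  binary expressed-vs-not truth by default — that is what thresholding
  produces — with the three-class variant available.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| EM relative log-likelihood tolerance | 1e-6 | `emFitGamma(tol=)` |
| Maximum EM iterations | 500 | `emFitGamma(maxIter=)` |
| Component-collapse floor on weights | 1e-4 | `emFitGamma(collapseTol=)` |
| Minimum positive cells to fit | 100 | `emFitGamma(minCells=)` |
| Initialization split | 80th percentile (+ bound split) | `emFitGamma(initSplit=)` |
| Boundary search bracket on shape | (1+1e-6, 1e3), tol 1e-8 | `constrainedMStep()` |
| Mode-tie perturbation | +1e-6 on scale, once | EM loop |
| Positive-call threshold | 0.5, ties positive | `thresholdPositive()` |
| Radius grid | 50 radii, translation correction | `radiusGrid()`, `ripleyH()` |

Problem sizes used by the recovery checks are part of the study design:
100 slides of 10,000 cells at $p = 0.05$, and 100 slides of 50,000 cells
at $p = 0.001$ (the larger slides control the Monte-Carlo error of a
50-cell expressed population).

## Interface notes and limitations

The package is driven from R; the exported functions, not a shell
executable, are its interface (reading tables and constraint files via
`readCellTable()`/`readConstraints()`, writing any output with ordinary R
tools). Only two-component fits are supported and tested, although the EM
accepts more components structurally. Constraints are deliberately
user-supplied — the method is semi-automated by design, and no automatic
constraint selection is attempted. K-function variants for inhomogeneous
intensity and non-rectangular windows are out of scope, as are image-level
operations (segmentation, registration, pixel features).

## A minimal session

```{r example, eval = FALSE}
ct <- readCellTable("cells.csv",
                    list(slide = "slide", cell = "cell",
                         markers = c("CD3", "CD68")))
ct <- normalizeMeanLog10(ct)
cstr <- list(unconstrained(), ModeConstraint(lower = 0.45))
fits <- fitBatch(ct, channels = "CD3", constraints = list(CD3 = cstr))
qcSummary(fits)                       # mode-vs-lambda diagnostic table
probs <- gateProbabilities(fits, ct)  # posterior + marginal per cell
calls <- thresholdPositive(probs$posterior)
```
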