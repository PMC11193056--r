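# mifGate

Semi-automated, probabilistic marker gating for segmented cell-level
multiplexed immunofluorescence (mIF) data.

After segmentation and quantification, an mIF experiment is a table of
cells × marker intensities spread over many slides. The gating question —
*which cells are positive for which marker?* — is usually answered either
by manual per-slide thresholding (subjective, slow) or by multivariate
clustering (hard to audit, unstable across batches). mifGate takes the
middle road for analysts who need reproducible, evaluable gating: a small
probability model fitted per slide and channel, steered by user-supplied
biological constraints, returning per-cell probabilities instead of hard
calls.

## The model

Each (slide, channel) stratum is a zero-inflated two-component Gamma
mixture,

    P(X = x) = I(x = 0) λ₀ + I(x > 0) Σₖ λₖ f(x; aₖ, bₖ),   k = 1, 2

with an exact point mass λ₀ at zero (an autofluorescence-adjustment
artifact), a marker-negative component with mode m₁ = (a₁−1)b₁ and a
marker-positive component with mode m₂ > m₁. Estimation is EM with a
**closed-form** weighted shape/scale estimator in the M-step (derived via
the generalized gamma family), which makes fitting hundreds of strata
fast and deterministic. The user constrains each component's mode to an
interval (fixed, or a quantile of the stratum's own distribution); a
violated constraint is handled exactly, by maximizing along the boundary
line (a−1)b = bound.

Each cell gets two probabilities of marker positivity: the posterior
λ₂f₂(x) / (λ₁f₁(x) + λ₂f₂(x)), monotonicity-corrected so it never
decreases with intensity, and the marginal F(x; a₂, b₂). Thresholding at
0.5 gives hard calls; averaging posteriors over a region gives soft
population proportions. Utilities cover batch fitting with QC and
convergence reporting, a batch-effect simulation generator with ground
truth, Ripley's K/L/H spatial statistics (univariate and cross-type), and
evaluation tools (phenotype assembly, Adjusted Rand Index).

## Worked example

Simulate a 3-slide batch with slide-to-slide parameter variation and 10%
expressed cells, fit it with an accurate elbow constraint, and inspect:

```r
library(mifGate)

sim  <- simulateSlides(pExpressed = 0.10, nSlides = 3,
                       nCells = 10000, seed = 1)
cstr <- scenarioConstraints("accurate", pExpressed = 0.10)
fits <- fitBatch(sim, constraints = cstr, assay = "intensity")
qcSummary(fits)[, c("slide", "mode1", "mode2", "lambda2", "converged")]
#>    slide      mode1     mode2    lambda2 converged
#> 1 sim001 0.13947011 0.9531748 0.10175427      TRUE
#> 2 sim002 0.15059612 0.9030542 0.09576497      TRUE
#> 3 sim003 0.05994345 0.8014150 0.09969714      TRUE
```

Each row is one stratum: the fitted negative/positive component modes and
the estimated marker-positive proportion λ₂ — here within half a
percentage point of the generating 10% on every slide, with the per-slide
batch variation visible in the modes. Per-cell probabilities and hard calls:

```r
probs <- gateProbabilities(fits, sim, assay = "intensity")
head(probs, 3)
#>    slide cell channel    posterior     marginal
#> 1 sim001    1  marker 2.097886e-11 5.101285e-12
#> 2 sim001    2  marker 0.000000e+00 0.000000e+00
#> 3 sim001    3  marker 2.374163e-08 2.580842e-09
calls <- thresholdPositive(probs$posterior)   # ties at 0.5 are positive
mean(calls)
#> [1] 0.0989
```

Cell 2 sits at exactly zero intensity, so both probabilities are exactly
zero; the thresholded positive fraction agrees with the simulated 10%.
Against the simulation's ground-truth labels,
`simulationReport(fits, sim)` reports per-slide bias of λ₂ and the
Adjusted Rand Index of the thresholded calls.

For real data, start from `readCellTable("cells.csv", schema)` and
`normalizeMeanLog10()`, then proceed identically; `convergenceReport()`
lists strata that failed to fit, whose probabilities propagate as `NA`.
The methods vignette (`vignettes/marker-gating-model.Rmd`) documents the
model, the closed-form estimator, the constraint machinery and the
simulation design in detail.

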