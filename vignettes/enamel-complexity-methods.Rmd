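---
title: "Quantifying occlusal enamel complexity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying occlusal enamel complexity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelD)
```

## The scientific problem

Hypsodont horses of the tribes Hipparionini and Equini chew abrasive
forage with teeth whose occlusal surfaces expose convoluted bands of
enamel. How convoluted those bands are is a functional trait, but ratio
indices of enamel length to tooth size retain allometric scaling:
larger animals have relatively longer enamel bands, so size leaks into
the complexity measure. The fractal dimension *D* of the band outline
is scale-free — a straight line has *D* = 1, a curve so convoluted it
fills the plane approaches *D* = 2 — which makes it the right
instrument for asking whether complexity itself differs between clades
and how it covaries with occlusal surface area once body size is off
the table.

enamelD implements that workflow end to end: binary traces of enamel
bands in, per-specimen *D* by box counting, species means, a Welch
*t*-test between tribes, and generalized least squares regressions of
*D* on occlusal area whose residual covariance is a phylogenetic
covariance matrix scaled by Pagel's λ, with λ estimated by maximum
likelihood on a fossil-calibrated tree.

## Box-counting estimator

`estimate_D()` composes three steps.

**Border extraction.** The method measures the exterior edge of the
enamel band, not its thickness: `extract_border()` keeps a foreground
pixel iff at least one of its 8 neighbours is background (the image
boundary counts as background). Filled bands reduce to one-pixel
outlines; already-thin traces pass through unchanged. 4-connectivity is
available behind a flag; 8-connectivity is the default because
diagonal-only contacts should not create interior pixels on a
one-pixel-wide digital curve.

**Covering counts.** For each box size *s* the image is partitioned
into an axis-aligned grid of *s* × *s* cells anchored at the image
origin, partial cells at the edges counting as cells, and `count_boxes()`
returns the number of cells containing foreground. The default ladder
is *s* ∈ {2, 3, 4, 6, 8, 12, 16, 32, 64} px — geometric spacing across
the classical 2–64 px range used by standard image-analysis
implementations of binary box counting. A single grid at (0, 0) is the
default, matching the classical procedure; `box_count_series()` can
instead average counts over *k* seeded random origins for robustness
studies.

**Log–log fit.** *D* = −slope of the ordinary least squares fit of
log *N*(*s*) on log *s* (the slope is negative because fewer large
boxes are needed; the log base cancels). The fit's R² is reported as a
quality diagnostic. Degenerate series (all counts equal) return
*D* = 0 with a warning rather than an error, since a one-box trace is a
legitimate, if useless, input.

**Known biases.** On finite rasters the estimator is biased low by a
few hundredths: at *s* = 2–3 a digital line "cuts corners" relative to
its continuous preimage, and at *s* = 64 partial boxes inflate counts.
On 729-px rasters the package's generators measure: straight lines
0.94–1.00 depending on angle, Koch curve (analytic 1.2619) ≈ 1.208,
Sierpiński arrowhead (analytic 1.585) ≈ 1.560, filled region ≈ 1.978.
All are within ±0.06 of the analytic values, which is the accuracy
band the test suite enforces; users comparing *D* across studies
should keep rasters and ladders consistent rather than trust absolute
third-decimal values. *D* is insensitive (< 0.05) to doubling the
raster resolution of the same generator curve, which is the property
that makes it usable across photographs of different sizes.

**Binarization polarity.** Traces are assumed dark-on-light: luminance
strictly below the threshold (default 0.5) is foreground. An 8-bit
gray value of 128 is therefore background at the default threshold
(128/255 > 0.5). `invert = TRUE` flips the rule for light-on-dark
material.

## Time calibration from stratigraphic ranges

Supertrees assembled from published phylogenies carry no usable branch
lengths. `time_calibrate()` dates them from first/last appearance data
(FAD/LAD, in Ma):

1. every internal node is placed at the oldest FAD among its
   descendant tips (deterministic max rule);
2. with `add_term = TRUE` (default) each terminal branch runs to the
   tip's LAD, so fossil tips end at last appearance and extant tips
   reach the present;
3. any remaining zero-length branch — inevitable wherever a node's age
   ties its oldest child — is opened by shifting the ancestral node
   older by `vartime` (default 1 Ma), the shift propagating rootward
   so no branch goes negative.

The ordering of steps 2 and 3 is a deliberate design choice: applying
the zero-length adjustment before extending terminals would shift
nodes to cure "zero" terminal branches that the LAD extension was
about to lengthen anyway, inflating node ages by `vartime` throughout.
Dating first, extending terminals, then repairing what is still
degenerate touches only the genuinely tied nodes. When several nested
nodes tie, each is pushed `vartime` older than its (already adjusted)
oldest child, so an *m*-deep stack of ties resolves to evenly spaced
nodes *m* × `vartime` above the tie age; no randomness is involved.
The resulting trees are generally not ultrametric, and
`phylo_covariance()` handles that: diagonal entries are root-to-tip
distances, off-diagonals the shared path length to the pair's most
recent common ancestor.

## GLS, PGLS and Pagel's λ

With species-mean data (PGLS requires species averages, since
within-species replicates are not independent draws on the
phylogeny), `gls_fit()` solves the V-whitened normal equations by
Cholesky factorization. Standard errors use the unbiased variance
estimate (RSS divided by *n* − 2); the reported log-likelihood is the
ML profile value used for λ estimation. R² is computed in the
whitened space against the intercept-only GLS fit, which keeps it
comparable across λ values; it reduces to the ordinary R² when V is
the identity.

`lambda_transform()` multiplies the off-diagonal of V by λ and leaves
the diagonal alone. λ = 0 therefore collapses PGLS to an
independent-error GLS (diagonal variances still proportional to tip
depth); λ = 1 is the full Brownian expectation.

`profile_lambda()` maximizes the ML log-likelihood over λ ∈ [0, 1]: a
21-point grid brackets the mode and a 1-D golden-section/Brent search
refines it to 10⁻⁶; the fit is then refitted at λ̂. The search is
bounded at 1 — values above 1 are not interpretable as signal strength
— and ties between the interior optimum and the endpoints resolve in
favour of whichever has the higher likelihood, so the maximized
likelihood provably dominates both endpoints. The 95% confidence set
is the profile-likelihood region {λ : log L(λ) ≥ log L(λ̂) − 1.92};
an endpoint lying on the [0, 1] boundary is reported as NA (no finite
bound), the convention of published λ tables. ML rather than REML is
used throughout, matching the 1.92-drop CI convention.
`lambda_signal()` applies the same machinery to an intercept-only
model to measure single-trait phylogenetic signal; on interior optima
it agrees with an independent implementation (phytools) to five
decimals, and differs only where the reference continues the search
past λ = 1.

Fitting is on a shared linear-algebra core, so the OLS limit is exact:
with identity covariance `gls_fit()` reproduces `lm()` coefficients,
standard errors, p-values and both R² to 10⁻¹⁰.

## Summary-level inference

Published species tables report per-species *n*, mean and sample SD.
`pooled_from_species()` reconstructs specimen-level moments exactly via
the variance decomposition
(Σ(nᵢ−1)sdᵢ² + Σnᵢ(mᵢ−m̄)²)/(N−1), so `welch_t()` on pooled group
statistics equals the Welch test that raw specimens would give. On the
packaged equid table the Equini side pools to 1.359 exactly as
printed; the Hipparionini side pools to ≈ 1.421 against a printed
1.430 — an internal inconsistency of the published comparison that the
package reports as computed rather than reproducing. The slope
comparison between two clades' regressions uses the classical
parallel-slopes *t* with n₁ + n₂ − 4 degrees of freedom.
Shapiro–Wilk and Bartlett pre-checks delegate to the standard
implementations in base R.

## What the synthetic generators emulate — and what they do not

`generate_curve()` produces the geometric extremes that anchor the *D*
scale (lines, plane-filling regions) and prefractals of known
dimension (Koch, quadric Koch, Sierpiński arrowhead). These validate
the estimator's accuracy but are not tooth-shaped: real enamel traces
are closed, multi-loop, anisotropic curves whose complexity sits in
the 1.2–1.6 range, and passing the geometric tests shows the estimator
is calibrated, not that any biological conclusion is automatic.
Iteration depths are chosen so the smallest segment is ~1–3 px,
keeping the whole 2–64 px ladder inside the self-similar regime
(defaults: Koch iteration 6 and arrowhead iteration 9 at 729 px); a
guard refuses configurations whose minimum feature falls below one
pixel.

`simulate_tree()` is a forward pure-birth simulation (exponential
waiting times, uniformly chosen splitter), run past the *n*-th split
to the moment the next split would occur so terminal branches are
never zero. Expected root-to-tip depth is (H(n−1) − 1 + 1/n)/birth,
which the tests verify by Monte Carlo. `simulate_traits()` draws the
predictor independently per tip and adds multivariate-normal residuals
with covariance σ² × λ-transformed V — exactly the model the
regression assumes, which is what makes parameter recovery a fair
test. `simulate_cohort()` wraps both and adds within-species specimen
noise with SD 0.05, the median within-species dispersion of the
packaged equid table, with 1–6 specimens per species as in
collection-limited fossil samples; its default regression parameters
(intercept 1.45, slope −0.016, λ = 0) mirror the magnitudes of the
equid analysis. Real data differ in ways the generator does not
attempt: non-Gaussian area distributions, correlated sampling effort,
and measurement error in area.

## Problem sizes and numerical choices

The test suite and the acceptance script run: 729–1458 px rasters;
50 random 128 × 128 images for the covering-count oracle; 100
replicates each for λ recovery under Brownian motion and after tip
permutation on a 64-tip tree; 200 replicates for slope recovery at
λ = 0; 1000 samples of n = 50 for the Shapiro–Wilk type-I rate; and a
30-species cohort for the end-to-end pipeline. These sizes give Monte
Carlo standard errors comfortably inside the asserted bands while
keeping a full run in the tens of seconds.

Other numerical choices: Cholesky-based whitening throughout (a
non-PD covariance raises an error rather than silently regularizing);
FAD ties in calibration broken by the deterministic max rule;
`count_boxes()` treats cells left/above a shifted origin as partial
covering cells; species names are normalized (quotes, asterisks,
underscores, whitespace) before any matching between tables and tree
tips, and taxa missing from the tree are dropped from phylogenetic
stages with a warning rather than an error, since indeterminate
open-nomenclature taxa are common in fossil tables.

## Limitations

- *D* estimates carry the finite-raster bias described above; the
  package reports the log–log R² so poorly scaling traces can be
  flagged, but it does not correct the bias.
- The λ search is bounded at 1; data preferring λ > 1 (more
  covariance than Brownian) pile up at the boundary.
- The zero-length-branch calibration is one defensible repair rule
  among several; stochastic calibration methods are out of scope, and
  trees whose FAD structure forces many nested ties deserve a
  sensitivity check over `vartime`.
- Welch reconstruction from summaries is exact only if the summary
  table is internally consistent; the packaged equid table is not on
  the Hipparionini side, and the package propagates the computed value
  rather than the printed one.
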