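# enamelD

Fractal complexity of occlusal enamel bands, on a phylogeny.

Hypsodont horses (tribes **Hipparionini** and **Equini**) expose
convoluted bands of enamel on the chewing surfaces of their teeth.
Ratio-based complexity indices (enamel length over √area) retain
body-size scaling; the **fractal dimension** *D* of the band outline
does not — a straight line has *D* = 1, a plane-filling curve
approaches *D* = 2 — so *D* lets complexity and tooth size be compared
on their own terms. enamelD is for palaeontologists and morphologists
who have binary traces of enamel bands (or any planar curve) and want
to (1) estimate *D*, (2) compare clades, and (3) regress *D* on
occlusal surface area while accounting for phylogeny.

## What it computes

**Box counting.** For box sizes *s* ∈ {2, 3, 4, 6, 8, 12, 16, 32, 64}
px, the one-pixel border of the trace is covered by an axis-aligned
grid and the occupied cells *N*(*s*) are counted; *D* = −slope of the
OLS fit of log *N*(*s*) on log *s*.

**Phylogenetic regression.** For species means, a GLS fit of
*D* on area with residual covariance σ²·V(λ), where V is the
shared-branch-length matrix of a time-calibrated tree and Pagel's λ
multiplies its off-diagonal. λ is estimated by maximum likelihood over
[0, 1] with profile-likelihood 95% CIs; at λ = 0 the fit collapses to
an independent-error GLS. Supporting machinery: fossil-range (FAD/LAD)
time calibration with a zero-length-branch adjustment, Welch *t*-tests
reconstructed exactly from species summary tables, slope comparison
between clades, Shapiro–Wilk/Bartlett pre-checks, and synthetic
generators (fractal curves of known *D*, pure-birth trees,
λ-structured traits) for validation.

## Worked example

Estimate *D* for a curve whose dimension is known analytically
(Koch curve, log 4 / log 3 ≈ 1.2619):

```r
library(enamelD)
g <- generate_curve("koch", iterations = 6, raster_px = 729)
estimate_D(g$trace)
#> D = 1.2083 (log-log R^2 = 0.9991, 9 box sizes)
```

The estimate sits within the ±0.06 band the estimator is validated to;
the high log–log R² says the trace scales cleanly across the ladder.

Reconstruct the tribe comparison from the packaged species summary
table (35 equid species, 98 specimens):

```r
s <- equid_species_summary()
eq <- pooled_from_species(s, "Equini")
hi <- pooled_from_species(s, "Hipparionini")
welch_t(eq, hi)
#> t = -3.791, df = 52.92, p = 0.00039  (means 1.359 vs 1.421)
```

Pooling is the exact variance decomposition, so these are the
statistics the raw specimens would give: Equini enamel bands are
significantly less complex than Hipparionini ones.

Full pipeline on a synthetic cohort with known truth
(λ = 0, slope = −0.016):

```r
coh <- simulate_cohort(n_species = 30, lambda = 0, slope = -0.016,
                       sigma2 = 5e-4, seed = 9)
rep <- run_pipeline(list(summaries = summarize_species(coh$specimens),
                         tree = coh$tree, seed = 9))
rep$regressions[rep$regressions$clade == "unified", ]
#>     clade lambda ci_lower ci_upper    slope       se      t      p ...  n
#>   unified      0       NA   0.4216 -0.01293 0.009784 -1.321 0.1971 ... 30
```

The ML λ is 0 (upper CI 0.42) and the generating slope −0.016 is
inside one standard error of the estimate. A thin command-line wrapper
(`inst/scripts/enameld`) exposes the same stages as subcommands
(`trace-d`, `summarize`, `compare`, `pgls`, `simulate`, `report`).

## Layout

- `R/` — trace I/O and binarization; box counting; tree calibration
  and covariances; GLS/PGLS/λ and summary statistics; synthetic
  generators; pipeline and CLI.
- `inst/extdata/equid_species_summary.csv` — packaged species summary
  (published measurements of 35 equid species).
- `vignettes/enamel-complexity-methods.Rmd` — model assumptions,
  estimator biases, calibration rules, design decisions, limitations.
- `tests/testthat/` — unit, property and oracle tests (brute-force
  cell enumeration, pixelwise border scans, normal-equations
  regression, MRCA path walks, independent λ implementation).
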