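---
title: "Models and methods behind spadefoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spadefoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadefoot)
```

`spadefoot` tests whether species-level life-history traits track climate,
trait covariates such as genome size, and phylogeny. This vignette records
the statistical models, the numerical decisions, and what the synthetic
data can and cannot tell you about real data.

## The phylogenetic covariance and its transforms

Every analysis starts from the Brownian tip covariance of a rooted
ultrametric tree: `V[i, j]` is the branch length shared by tips *i* and
*j* from the root, and the diagonal is the tree depth *T* (Myr).
Ultrametricity is checked at a relative tolerance of 1e-6 on root-to-tip
depths — chronograms are exactly ultrametric in principle, but branch
lengths written through finite-precision Newick text drift at around the
tenth digit, which is noise, not signal. Polytomies and zero-length
branches are accepted; they only change shared path lengths.

Two transforms reshape `V`:

* **Pagel's lambda** multiplies off-diagonals by λ ∈ [0, 1]. λ = 1 is
  Brownian motion; λ = 0 is a star phylogeny. The result is a convex
  combination of `V` and `diag(V)`, hence positive semi-definite on the
  whole interval. We restrict λ to [0, 1]: values above 1 are
  mathematically admissible on some trees but rarely interpretable, and
  the restriction matches the convention of the standard PGLS tooling this
  package mirrors. The consequence — boundary estimates at exactly 0 or
  1 — is handled explicitly everywhere (endpoint checks in optimization,
  boundary-aware tests for signal).
* **Ornstein–Uhlenbeck** with restraining force α > 0 (per Myr):
  `V[i, j] = (1/2α) · exp(−2α(T − s_ij)) · (1 − exp(−2α s_ij))`, the
  transform that treats the root state as the optimum with variance
  accumulating from zero. The literature contains several OU variants
  (stationary root, estimated root state); this one is pinned as the
  package's choice because it is the classical single-optimum transform
  and reduces exactly to Brownian motion as α → 0, which the tests verify
  by series expansion. The scale σ² is never baked into the matrix; it is
  concentrated out of the likelihood analytically.

Cholesky factorization is the only decomposition used (no explicit
inverses or determinants). Matrices that lose strict positive definiteness
to rounding get a diagonal jitter of at most 1e-10 × mean diagonal before
the operation is abandoned with an error.

## Single-trait model fits and model choice

For one trait, `fit_bm`, `fit_ou` and `fit_lambda` maximize the Gaussian
likelihood `y ~ N(mu·1, sigma2·V(shape))`. Given the shape parameter, the
mean and rate have closed forms (GLS mean; ML rate with divisor *n*, not
*n* − 1 — REML rates would not be comparable across models under AIC, and
AIC comparison is the point). Only the shape is profiled numerically:

* λ by bounded one-dimensional optimization on [0, 1] at tolerance 1e-8,
  with the endpoints evaluated explicitly because the profile maximum
  frequently sits on the boundary;
* α on the log scale over [1e-4/T, 100/T] — below the lower bound the OU
  model is numerically indistinguishable from Brownian motion, above the
  upper bound covariance between even sister tips has decayed to nothing.
  The α profile can be flat or multimodal, so `fit_ou` launches 10 local
  quasi-Newton optimizations from random log-uniform starts and keeps the
  fit with minimum deviance (−2 log L). Ten restarts is the package
  default because the α profile on trees of this size has at most a few
  basins; the start points derive deterministically from a user seed
  (default 20140506) so fits are reproducible. A global bounded search
  (Brent) would make restarts vacuous, which is why a local optimizer is
  deliberate here.

`model_table` compares the three fits by AIC (= −2 log L + 2k; k = 2 for
BM, 3 otherwise) and reports as "preferred" every model within 4 AIC units
of the best — the conventional threshold below which support is treated as
equivocal. Constant traits are flagged degenerate rather than fitted.

## PGLS

`gls_fixed` whitens response and design with the Cholesky factor of the
error covariance and runs OLS in the whitened space. R² is variance
explained relative to the *phylogenetic-mean-only* model in that same
space — the definition used by the standard PGLS implementations — and the
slope test is F = (n − 2)·R²/(1 − R²) on (1, n − 2) df. With the identity
covariance everything collapses to textbook OLS, which the tests check to
1e-10.

`pgls_ml_lambda` re-estimates λ jointly for every regression by profile
likelihood (never reusing a single-trait estimate: the λ that matters is
that of the *residuals*). `pgls_ou` estimates α from the response variable
alone via `fit_ou` and then runs the regression under the fixed OU
covariance. Estimating α from the response rather than the residuals or
the predictor is a pinned design choice: it keeps the transform
independent of the fitted slope, and a sensitivity analysis can simply
pass the predictor instead. Missing values are dropped pairwise
(complete-case per regression) with the tree pruned to match, and each
report row carries its own *n*, since trait coverage commonly varies
(genome sizes are typically available for fewer species than life-history
measurements).

## Phylogenetic signal

`pagels_lambda` reports the ML λ per trait plus likelihood-ratio tests
against λ = 0 and λ = 1. Because λ̂ can sit on the boundary of the
parameter space, the χ²₁ p-value is halved (the 50:50 mixture convention);
the convention is recorded in the result's metadata. Near-zero estimates
are reported as-is in scientific notation, never floored — an estimated
λ of 4e-07 is a statement that the trait is phylogenetically free, and
rounding it to zero would discard the evidence that the optimizer reached
an interior solution.

## Climate reduction and aridity

Locality vetting collapses duplicates by exact coordinate equality after
rounding to 4 decimal places (~11 m — "the same locality" is otherwise
undefined for museum records), drops records flagged outside the published
range, and drops records with elevations outside the configured bounds;
records with no elevation pass that filter with a logged note. Every
rejection carries a reason code, and a species losing all its records is
an error, not a silent omission.

Species summaries are min/max/mean/midpoint per bioclim variable. The
aridity index is Q = P/((Tmax + Tmin)(Tmax − Tmin)): `logQ` uses the mean
annual precipitation with range-extreme temperatures (max bio5, min bio6),
`logQ2` the quarter-mean temperatures (mean bio10, bio11). Q is analyzed
on the log₁₀ scale (the convention of the aridity-index literature;
natural log sits behind a flag). Two unit decisions are explicit because Q
is not invariant to them: temperatures must be declared `"celsius"` or
`"worldclim-raw"` (WorldClim 1.x stores °C × 10; the reader rescales by
0.1), and a negative Q (possible when Tmax + Tmin < 0) is a hard error
rather than a NaN, because a log-aridity value computed from a
sign-flipped denominator is meaningless.

## Calibration priors

The offset-lognormal node-age prior interprets "mean" in real space (the
BEAUti convention): age = offset + L with log L ~ N(ln m − s²/2, s²),
so the real-space mean of the unshifted lognormal is exactly m. This is
the only reading under which published calibration intervals of this form
reproduce, and the tests pin it. `prior_interval` defaults to the 5th–95th
percentile span, which is what dating papers commonly print as the "95%"
prior interval (a display convention, not a central 95% interval; the
quantiles are exposed directly so either can be computed).

## What the synthetic data emulates — and what it does not

`make_study_fixture` generates the study design the analysis assumes: a
16-species pure-birth tree of depth 150 Myr; minimum larval periods (days)
under Brownian motion; minimum hatching times regressed on larval period
with λ-structured residuals (defaults β₁ = 0.15, residual λ = 0.6, chosen
to give a clearly detectable but not deterministic relationship at n =
16); midpoints at or above minima; genome sizes (pg) with near-Brownian
signal and only 8 of 16 species covered, to exercise complete-case logic;
and museum-style locality tables with 3–322 records per species
(log-uniform counts, matching the right skew of real record databases)
scattering around species-level climate centres that themselves carry
phylogenetic signal — except precipitation seasonality, which is generated
iid across species because that is the one climate variable real data
show to be phylogenetically free. Sub-seeds fan out deterministically from
one master seed (`(seed · 7919 + stream) mod 2³¹ − 1`), so the fixture is
bit-reproducible and stages can be regenerated independently.

What it does *not* emulate: spatial autocorrelation of climate between
neighbouring localities (records scatter independently around the species
centre); measurement error and georeferencing error in trait or locality
values; within-species covariation between life-history and the locality
it was measured at (the "matched locality" column is a noisy copy of the
minimum, not a mechanistic link); and non-Gaussian trait distributions.
Passing tests on this fixture therefore demonstrate that the estimators
recover the structure they model, not that real trait–climate data meet
the model's assumptions.

## Simulation sizes and numerical tolerances

The test suite's simulation studies use sizes chosen to make Monte-Carlo
noise small relative to the assertion being made: parameter recovery for
λ uses 200-tip trees × 50 replicates per λ level (λ̂'s sampling sd at
n = 200 is ≈ 0.1, so a mean-absolute-error bound of 0.15 is a real
constraint); OU slope recovery uses 100-tip trees × 100 replicates; the
type-I-error study uses 2000 replicates at n = 16 (binomial se ≈ 0.005 at
a rate of 0.05); distributional checks on the tree simulator pool split
times from 400 trees per simulator. Optimization tolerances are 1e-8
(profile λ) and `nlminb` defaults on log α; grid cross-checks use 1001
points, so agreement is asserted at 1e-3, the grid's own resolution.

## Known limitations

* **Jointly estimated λ inflates the PGLS test at small n.** With 16 taxa
  and Brownian predictors and residuals, the F-test after ML-λ estimation
  rejects a true null at about 0.09 rather than 0.05 (the suite's
  2000-draw check computes this; with the true covariance fixed the same
  draws reject at the nominal rate). This is a property of the method —
  the test does not account for the estimated covariance parameter — and
  users should read borderline p-values near 0.05 at n ≈ 16 accordingly.
  An independent unconstrained-λ GLS implementation is substantially more
  anticonservative still, so the [0, 1] constraint helps but does not
  cure it.
* Single-optimum OU only; no multi-regime models, early-burst, trends, or
  measurement-error variance.
* The λ search domain stops at 1; traits genuinely more similar than
  Brownian expectation among relatives are reported as λ̂ = 1.
* Climate vetting consumes a precomputed range flag; point-in-polygon
  range tests and raster extraction are upstream concerns.
* No multiple-testing correction is applied anywhere, by design: the
  batteries mirror analyses that report raw per-pair p-values, and the
  report footer says so.
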