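---
title: "Methods: spectral analysis of drying Sphagnum libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral analysis of drying Sphagnum libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphagspec)
```

This vignette documents the models, conventions and numerical choices behind
`sphagspec`, in the spirit of a methods section: what each stage computes,
which knobs matter, and where genuinely open design decisions were settled.

## The measurement model

A spectral library couples a reflectance matrix (records × wavelengths) with
per-record metadata on one shared grid, 350–2500 nm at a 1 nm step (2151
points) by default. Records follow a `species_replicate_time` id convention,
and the two-group habitat partition is a closed-world pure function of
species: the richer-site species (*S. centrale*, *S. girgensohnii*,
*S. riparium*, plus *S. fallax*) form the mesotrophic group; the bog and
oligotrophic species (*S. cuspidatum*, *S. fuscum*, *S. rubellum*, plus
*S. angustifolium*) form the oligo-ombrotrophic group; *S. capillifolium*,
collected from peatland-edge ecotones, stays outside the division and is
excluded from every habitat-level computation. Unknown species names are
rejected rather than coerced, because silent coercion would corrupt that
partition.

Raw spectroradiometer acquisitions are triplets: the sample reading, a white
reference, and a dark current. Reflectance is the dark-corrected ratio
scaled by the reference panel's reflectance factor (nominally 0.99 for the
Spectralon panel assumed here),

$$\mathrm{CCRF} = \frac{I_s - I_{dc}}{I_{wr} - I_{dc}}\,RF_{wr}.$$

Three conventions are worth stating. First, repetitions of one acquisition
are averaged *before* the ratio. Second, each sample uses the
reference pair nearest in time, ties resolved toward the earlier pair;
interpolation between hourly references would be an alternative, but
nearest-in-time is reproducible, conservative, and configurable. Third,
negative reflectance values — detector noise around near-zero signal, which
genuinely occurs for the darkest moss in the visible and shortwave infrared —
are retained and merely counted in a QC attribute; clipping them at zero
would bias exactly the darkest samples.

Smoothing is Savitzky–Golay with a 25 nm window. At the 1 nm step that is 25
grid points; the polynomial order is 2, a common choice for reflectance work
that preserves absorption-feature shape (the order is exposed as an
argument). Edges are handled by evaluating the polynomial fit of the
first/last full window off-centre, which keeps the filter exact for
polynomials up to its order over the whole vector — verified in the tests on
a quadratic. Detector-splice correction is deliberately not applied: the
libraries this package targets are already splice-corrected upstream.

## Moisture bookkeeping

Gravimetric moisture is computed per sample and measurement time as
$\mathrm{Moist} = (F_w - D_w)/F_w$, with $F_w$ the container-free fresh mass
and $D_w$ the sample's single final dry mass (shared across its measurement
times, matching the protocol of weighing once after complete drying).
Species × time summaries report the *mean of per-sample moistures*, not the
moisture of mean masses: the two differ by a Jensen gap whenever masses
vary between samples, and only low-variance species agree under both
conventions at one decimal. The summary's mass column is the container-free
sample mass $F_w$ — whether published summaries of this kind include the
container is usually unstated, so the assumption is documented here and in
the shipped mass table's docs. Percentages are reported at one decimal.

## Band statistics

**Wilcoxon significance bands.** Fresh (0 h) vs week-dried spectra are
compared per wavelength with a two-sided *unpaired* rank-sum test at
α = 0.05. Two faithful-reproduction choices: the test is unpaired even
though the design is repeated-measures, matching the naming convention of
the analysis being reproduced; and no multiple-testing correction is applied
across the 2151 wavelengths — each band is tested at a raw 5% level
(a Benjamini–Hochberg switch exists but is off by default). P-values are
exact for group sizes up to 12 when the data are tie-free, otherwise the
normal approximation with tie correction is used; all-tied data give p = 1
by convention. Maximal runs of significant wavelengths are reported as
contiguous regions that exactly partition the significant bands.

**Red-edge inflection point.** The REP is the wavelength of steepest
reflectance rise in a 680–750 nm window, computed as the maximum first
central difference on the smoothed spectrum, ties broken toward the lowest
wavelength, with a flat window an explicit error. The literature's REP
algorithms vary (polynomial fits, Gaussian fits, four-point interpolation);
the derivative method is the package's documented default because it is
assumption-free on the peak shape, and the classical four-point linear
interpolation variant is available as `method = "linear_four_point"`.

**Variance decomposition.** Per wavelength, reflectance is regressed on a
categorical factor by least squares; for a one-way layout the coefficient of
determination reduces to $R^2 = SS_{between}/SS_{total}$, which is how it is
computed (vectorised over wavelengths). The species factor uses all nine
species; the habitat factor drops the excluded ecotone species first.
Zero-variance wavelengths get $R^2 = 0$. Because habitat coarsens species
over the eight assigned species, species-$R^2 \ge$ habitat-$R^2$ holds
pointwise there; the tests assert it. The decomposition is fit per
measurement time by default — pooling times would mix drying variance into
the between-species signal.

## Multivariate structure

PCA is run per measurement time on centred spectra, scaled per wavelength to
unit variance by default (raw-covariance PCA by flag; scaling is the default
of the common multivariate toolkits this workflow mirrors, which do not
always say so — it is flagged here as a reproduction-sensitive choice).
Constant wavelengths are left unscaled rather than dropped. Component signs
follow a fixed convention — the largest-magnitude loading of each component
is positive — so scores are reproducible across record orderings and BLAS
builds up to that convention.

Clustering is agglomerative with Ward linkage (`ward.D2`, i.e. Ward on
Euclidean distances) on the first three score columns, cut at k = 3. Both
n_pc = 3 and k = 3 are defaults bound to the observation that three
components carry >90% of the spectral variance in libraries of this kind;
linkage is likewise a reproduction-sensitive default with complete/average
available. Cluster composition tables report per-cluster majority purity;
records outside the habitat division are excluded from the purity
denominator.

## The ratio-index scan

For each measurement time the scan computes RI = R(λ₁)/R(λ₂) for every
ordered pair on the (optionally strided) grid and regresses RI on moisture
percentage. Conventions:

- **Moisture in percent (0–100)**, so slopes are "per percentage point".
- **RMSE uses the n denominator** (root mean squared residual), not n − 2;
  the choice is documented and tested against a closed-form oracle.
- **Both triangles are computed**: swapping λ₁ and λ₂ maps RI to 1/RI, a
  nonlinear transform under which R² is not invariant (the tests exhibit a
  witness), so neither triangle is redundant.
- **Diagonal** pairs have constant RI = 1 and carry R² = 0 (zero-variance
  response, slope 0).
- **Masking**: denominator bands where any sample's |R| < 1e-4 are masked
  entirely — near-zero denominators from very dark samples produce unstable
  ratios that would dominate the argmax spuriously.
- **Ties** for the best pair break toward the lowest λ₁, then the lowest λ₂.

The surfaces are vectorised per denominator band through the correlation
identity $R^2 = \mathrm{cor}(RI, m)^2$ together with closed-form OLS
(slope from covariances, RMSE from $SS_y(1 - R^2)/n$), so the full-grid scan
is O(P²·N) floating-point work with no per-pair model objects; a stride
argument makes cheap scans cheap. `surface_summary()` reports connected
components (4-neighbour) of the thresholded R² surface as bounding boxes.

## What the synthetic generator does and does not emulate

The generator exists so that every stage of the pipeline — and every claim
in the test suite — runs without downloads. It emulates the study design
(9 species × 10 replicates × 4 measurement times) and the statistical
structure the analyses assume, not radiative transfer:

- **Spectra**: per species, a visible baseline with pigment wells (450,
  670 nm) and a green peak (550 nm), a logistic red edge with
  species-specific inflection (mesotrophic species ~717–722 nm,
  oligo-ombrotrophic ~698–704 nm), a NIR plateau with a gentle SWIR decline,
  and Gaussian liquid-water wells at 970/1160/1450/1940 nm whose depths
  scale *linearly with the current moisture fraction*. A per-sample
  lognormal brightness factor multiplies the whole spectrum (so band ratios
  cancel it), and additive Gaussian measurement noise (sd 0.002) sits on
  top. Any parameterisation that pushes reflectance outside (0, 1) is an
  error naming the species and time, not a silent clip.
- **Drying**: each sample's water mass decays exponentially,
  $W(t) = W_0 e^{-rt}$, so moisture $\theta = W/(W + D_w)$ is non-increasing
  by construction. The per-species defaults (initial moisture 0.87–0.99,
  e-folding rates 0.024–0.266 per day, dry masses) are fixed once from the
  published per-species mass summary shipped with the package, which makes
  the generator's default conditions the drying experiment's conditions:
  fen species dry hard within a week, bog species barely dry, and the
  default one-week moisture spans roughly 0.5–0.99. Moisture loss also
  *bleaches* the spectrum (baseline lift of 0.25 per unit moisture-fraction
  loss by default), emulating the whitening of drying moss that brightens
  the visible/NIR/SWIR.
- **Masses**: generated by inverting the moisture equation
  ($W_0 = D_w\,\theta_0/(1-\theta_0)$ plus a fixed 50 g container), so
  applying `moisture_content()` to the generated mass table reproduces the
  planted moisture fractions to machine precision — an identity the tests
  assert. Initial-moisture jitter acts on the log-odds scale so that
  near-saturated species keep realistic mass spreads.
- **Determinism**: one global seed; per-species sub-streams derived from it;
  the caller's RNG state is saved and restored.

What it does not emulate: instrument line-shape and splice artefacts,
anisotropy/BRDF effects, biochemical covariation between pigments and water,
within-sample spatial heterogeneity, and any nonlinearity of the
moisture–absorption relationship. Consequently, passing tests demonstrate
that the *algorithms* recover planted structure of the kind the analyses
assume (linear moisture–absorption coupling, habitat-differentiated drying,
species-specific red edges); they do not certify performance on measured
libraries, which the separate full-reproduction test track covers when a
measured deposit is available locally.

All per-replicate jitters (brightness, initial moisture, drying rate, dry
mass) scale with the one `intraspecific_cv` knob (default 0.08), so setting
it to zero with zero noise produces exactly identical replicates — a useful
degenerate case the tests exploit.

## Problem sizes used by the test suite

The suite runs entirely on synthetic or hand-built data. The standard
fixture is the full design at 4 replicates (144 records); design-arithmetic
checks use 10 replicates (360 records). The planted-well recovery study
uses 20 seeds × (9 species × 10 replicates) with the ratio-index scan at a
5 nm stride over the full grid (431 bands, ~186k pairs per seed), and the
habitat-clustering study uses 20 seeds of the full design — sizes at which
the stochastic claims (≥90% of seeds recover the 1450 nm well within 60 nm;
median best-cluster habitat purity ≥0.9) are stable. Full-grid scans at
stride 1 (4.6M pairs) run in a few minutes and are exercised through the
same code path.

## Known limitations

- The Wilcoxon stage tests each wavelength independently; neighbouring
  bands are strongly correlated, so region boundaries are descriptive, not
  inferential.
- The REP derivative method quantises to the grid step (1 nm) and can sit a
  few nm off the true inflection when pigment-well tails overlap the search
  window.
- The scan's linear RI–moisture model is the analysis being reproduced;
  exponential or saturating moisture responses are out of scope, and R²
  surfaces will understate such relationships.
- `fit_ri_on_moisture()` reports R² as squared Pearson correlation, which
  coincides with the OLS coefficient of determination for simple linear
  regression only — the only case used here.
- The pipeline caches only the ratio-index stage (keyed by config hash);
  all other stages are cheap enough to recompute.
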