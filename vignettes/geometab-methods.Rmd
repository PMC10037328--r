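---
title: "Models and methods behind geometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geometab)
```

`geometab` maps the spatial structure of a crop metabolome: metabolites are
quantified per field position from 1D ¹H-NMR spectra, collapsed into a
per-site metabolic index, and analyzed geostatistically. This vignette is
the package's own account of the models it implements, the parameters that
matter, the design choices that were genuinely open, and what the synthetic
data do and do not establish.

## 1. The NMR signal model

A free induction decay is modelled as a sum of decaying complex
exponentials, one per multiplet component line,

$$s(t) = \sum_k A_k \sum_c r_c \exp\{(2\pi i f_{k,c} - \pi w)\, t\},$$

where $f_{k,c}$ is the component frequency (catalogued chemical shift plus
the J-coupling offset, converted to Hz at the spectrometer frequency), $w$
the linewidth (FWHM, Hz) and $r_c$ the fixed relative component
intensities. Fourier transformation of a one-sided exponential gives a
Lorentzian, which is why the quantification model (below) is Lorentzian
too: synthesis, apodization and fitting are mutually consistent.

Component patterns follow the four shape codes of the signal catalogs:
singlet (one line), doublet (two lines split by $J$, 1:1),
doublet-of-doublets (four lines at $\pm(J_1 \pm J_2)/2$, 1:1:1:1) and the
1:4:6:4:1 quintet (five lines at spacing $J$). The catalogs give no
coupling constants, so defaults are package choices: 7 Hz for `d` and `5m`
(a typical vicinal ¹H–¹H coupling) and (7, 3) Hz for `dd`; equal couplings
would degenerate a `dd` into a triplet, hence the asymmetric default. These
are starting values — deconvolution refines them within ±3 Hz bounds.

Amplitudes are calibrated so that one amplitude unit equals one unit of
integrated intensity on the ppm axis after transformation; the zero-noise
round trip (synthesis → processing → deconvolution) returns the input
amplitudes to within 0.5%, which the test suite asserts.

Default acquisition parameters are a 600.13 MHz instrument, a 12 ppm sweep
centered at 4.7 ppm and 16384 complex points (≈ 2.3 s acquisition). At the
default 0.8 Hz intrinsic linewidth plus 0.3 Hz broadening, the FID decays
to ≈ 4·10⁻⁴ of its initial amplitude before truncation; tests that fit
linewidths of 0.3 Hz or probe sub-0.001-ppm lineshape agreement use 32768
or 65536 points instead, because truncation ripple is the dominant
numerical artifact at shorter acquisitions.

## 2. The processing chain

`apodize → transformSpectrum → phaseCorrect/autoPhase → baselineCorrect →
calibrateSpectrum`, each a pure function.

* **Apodization** multiplies sample $k$ by $e^{-\pi\,\mathrm{lb}\,t_k}$,
  adding `lb` Hz of Lorentzian width; 0.3 Hz is the conventional value for
  profiling spectra and the default.
* **Transformation** zero-fills to a power of two (doubling the acquired
  length by default — one conventional zero-fill, no linear prediction, so
  the FFT stays an exact representation of the data), halves the first
  point to suppress the one-sided-sequence DC offset, and maps frequency to
  ppm through the carrier.
* **Phasing** applies $e^{-i(\phi_0 + \phi_1 (k - k_{pivot})/N)}$ with the
  pivot at the axis center. The automatic mode minimizes the integrated
  squared negative intensity — the standard objective for absorption-mode
  spectra — over a coarse grid refined by Nelder–Mead. No claim of
  optimality is made beyond the contract the tests check: a spectrum
  dephased by a known $(\phi_0, \phi_1)$ is returned to < 1% negative
  intensity.
* **Baseline** is estimated by asymmetric penalized least squares (AsLS)
  with asymmetry $p = 0.001$, smoothness $\lambda = 10^7$ and 10 weight
  iterations, a banded sparse solve per iteration. The reference tool used
  for the original spectra is closed-source, so AsLS was chosen as the
  standard, fully parameter-documented alternative; the contract (known
  smooth baselines recovered to 2% of the maximum peak, line integrals
  preserved to 1%) is what the tests pin down.
* **Calibration** finds the tallest peak within ±0.5 ppm of 0 ppm, refines
  its center by a local Lorentzian fit, and shifts the whole axis rigidly
  so that center lands on the DSS reference (0.015 ppm in these buffered
  extracts). Candidate peaks must exceed 5× a robust noise estimate;
  failure reports the search window.

## 3. Quantification by multiplet deconvolution

The unit-area component Lorentzian is

$$L(\delta) = \frac{2}{\pi w}\,\frac{1}{1 + 4(\delta - \delta_0)^2/w^2},$$

with $w$ the FWHM in ppm. A multiplet ties all its components to **one
center, one FWHM and one total area** (components carry the fixed relative
intensities), which is what keeps the crowded polysaccharide cluster at
5.38–5.44 ppm identifiable: six doublets whose components interleave within
a few Hz cannot be fit as free lines.

Multiplets whose windows (outermost component ± 10 initial FWHM) intersect
are fit **jointly** in one window by Levenberg–Marquardt with box bounds:
centers within ±0.01 ppm of the catalog shift (the same tolerance used for
annotation), FWHM in [0.05, 25] Hz starting at 1 Hz, areas ≥ 0 (negative
iterates clamp at zero), couplings within ±3 Hz of the catalog value.
Areas are initialized from the intensity at the tallest component; the
optimizer runs to a relative cost tolerance of 10⁻¹⁰. Non-convergence is
flagged per row, never silently dropped.

Annotation matches each catalog entry to the nearest local maximum within
0.01 ppm. Maxima below 0.5% of the tallest intensity are ignored: on real
spectra the 5×noise floor dominates, but noise-free synthetic spectra have
truncation sidelobes instead of noise, and the relative floor suppresses
those equally well. Two entries claiming the same maximum are both flagged
ambiguous; a sample in which more than half the catalog cannot be matched
is excluded from the concentration matrix and reported.

The "area" reported is the total multiplet area (not the tallest
component's), the natural reading of line integrals for tied multiplets.

## 4. Metabolic indexes

With $z_{ij} = (x_{ij} - \mu_j)/\sigma_j$ (population $\sigma$, i.e.
divide by $n$ — the standard-scaler convention, used consistently so that
"index variance = top eigenvalue" holds exactly), the index is
$MI_i = \sum_j w_j z_{ij}$ with

| scheme | $w_j$ | emphasis |
|---|---|---|
| mean | $1/N$ | all metabolites equal |
| CoV | $\mathrm{CoV}_j / \sum_j \mathrm{CoV}_j$ | high relative variability |
| PCA | PC1 loadings | variance among sites |

CoV is computed on the **raw** concentration scale: after standardization
every $\mu_j$ is zero and $\sigma/\mu$ is undefined, so weighting raw-scale
relative variability and applying the weights to standardized variables is
the only self-consistent reading. Metabolites with exactly zero raw mean
are excluded with a warning. PC1's sign is fixed by making the largest
|loading| positive — a pure convention, since loadings are sign-ambiguous;
ties in the top eigenvalue (within 10⁻⁹) warn and resolve
deterministically. The full metabolite set is always used; no Moran-based
pre-selection of "spatial" metabolites is applied, since a defensible
threshold does not exist and all catalogued metabolites carry spatial
signal in practice.

## 5. Geostatistics

* **Projection.** WGS84 geographic coordinates are projected with the
  transverse-Mercator Krüger series in the third flattening to order $n^6$
  (zone 34N, central meridian 21°E, $k_0 = 0.9996$, false easting
  500 km). The test suite checks it against an independently constructed
  oracle (meridian arc by numerical quadrature, correction coefficients by
  Fourier analysis — no shared constants) to < 1 mm and round-trips the
  inverse to < 10⁻⁶ m. Note the two built-in field locations lie west of
  the zone-34 strip; the series remains sub-millimeter accurate there.
* **Spatial weights.** Triangular kernel
  $w_{ij} = \max(0, 1 - d_{ij}/h_i)$ with adaptive bandwidth $h_i$ = exact
  distance to the k-th nearest neighbour (k = 7 default). A site exactly at
  the bandwidth gets weight 0, and $w_{ij} \neq w_{ji}$ in general — both
  are inherent to adaptive kernels, not bugs. Row standardization is ON by
  default (the convention of the spatial-econometrics libraries this
  mirrors); both behaviors are selectable, and the global statistic is
  invariant content-wise under either in the tests' brute-force checks.
* **Moran's I and LISA.** $I = (n/S_0)\sum_{ij} w_{ij} z_i z_j / \sum z_i^2$;
  $I_i = (z_i/m_2)\sum_j w_{ij} z_j$. Significance is by random relabeling
  (conditional on site $i$ for LISA), two-sided around the expectation
  $-1/(n-1)$, with the $(x+1)/(m+1)$ p-value estimator — its permutation
  size is exact, which the suite verifies over 400 i.i.d. replicates
  against the binomial acceptance region.
* **Variography.** Matheron's estimator in 20 equal-width bins on
  $[0, d_{max}/2]$; empty bins drop. The exponential model is fit by
  weighted least squares (weights = pair counts) with bounds
  $c_0 \ge 0$, $c > 0$, $\ell \in (0, 10\,h_{max}]$. The reported
  correlation length is the **length-scale parameter ℓ**, with the
  effective range $3\ell$ printed alongside, because reported correlation
  lengths in the field ambiguously mean either.
* **Flat variograms.** A fit is flagged *flat* (no usable spatial
  structure) when the partial sill is < 5% of the total, when the modelled
  rise over the observed lags is < 5% of the mean semivariance, when ℓ
  collapses below half the first bin (numerically a pure nugget), or when
  ℓ pins at the upper bound with < 20% resolved rise. Kriging refuses a
  flat model; the pipeline then falls back to deterministic thin-plate
  interpolation, mirroring standard practice when kriging is impossible.
* **Kriging.** The ordinary-kriging system in semivariance form (data
  semivariance matrix bordered by the unbiasedness constraint) is solved
  once per variable for all grid nodes; weights sum to 1 to 10⁻¹⁰ and the
  kriging variance $\lambda^\top\gamma_0 + \mu$ is reported. With zero
  nugget the predictor interpolates exactly.
* **RBF.** Thin-plate spline $\phi(r) = r^2\log r$ with an affine term,
  solved on **centered** coordinates: the interpolant is translation
  invariant, but at raw UTM magnitudes (northing ≈ 4.5·10⁶ m) the
  augmented system is numerically singular, so centering is a conditioning
  necessity, not a modelling choice.
* **Diagnostics.** Sturges histograms, Gaussian KDE with Silverman's
  bandwidth, and normal Q–Q pairs at plotting positions $(i-0.5)/n$.

## 6. The synthetic-data generator

The generator is the package's ground truth, and its defaults describe the
study conditions the pipeline targets:

* positions on a quasi-grid over a 500 × 200 m field, jittered with ~3 m
  isotropic Gaussian GPS error (converted to degrees by the local metric at
  the field origin — at 3 m the flat-earth approximation errs negligibly);
* stationary GRFs with exponential covariance, simulated by dense Cholesky
  factorization — exact, and entirely adequate at ≤ ~1000 sites; no
  FFT-based approximation is used;
* bimodal metabolite patterns built by thresholding a latent GRF at the
  empirical $(1 - f_{hi})$ quantile, the simplest construction that yields
  spatially clustered membership with exact mode fractions (defaults:
  modes −0.5 and 2.0 with the smaller high-mode fraction 0.3, the
  shape of the strongly clustered metabolite distributions the pipeline is
  designed to detect);
* synthetic spectra from the signal catalogs, with an optionally mis-set
  DSS position to exercise calibration.

What the synthetic data **do not** emulate: inter-metabolite correlation
beyond what is explicitly injected, per-metabolite noise heterogeneity
(neither is documented for the real fields, so both are free parameters
left at independent defaults), solvent suppression and other hardware
effects (synthetic spectra simply omit a solvent line), non-Lorentzian
lineshape distortions (shimming, susceptibility), and any temporal
dimension. Passing tests therefore establish the *correctness of the
machinery* under the stated models — not that real-field estimates share
these error bars.

## 7. Numerical choices and degenerate inputs

Optimizer tolerances: 10⁻¹⁰ relative cost for deconvolution, 10⁻¹² for the
variogram WLS (500 iterations max). Covariance factorization failures
report the offending minimum eigenvalue and suggest a nugget. Constant
fields are rejected by Moran/LISA (the statistic is undefined), return
all-zero variograms, and krige to the constant exactly. Duplicate
coordinates are rejected by weights, kriging and the GeoDataset validity
check, naming the pair. Zero-variance metabolite columns are excluded from
standardization with a warning and recorded in the result. Permutation
seeds are explicit arguments everywhere; the pipeline derives per-variable
seeds from the config seed, and a rerun with the same config is
byte-identical.

Problem sizes in the test suite are desk-scale by design: 150-site fields
and 20 seeds for variogram recovery, 400 replicates × 199 permutations for
the test-size check, a 60-site × 6-signal study for the end-to-end
bimodal-recovery run. These sizes make the full suite complete in well
under a minute of compute per heavy test while keeping Monte-Carlo error
well inside the asserted tolerances.

## 8. Known limitations

* Only the four catalogued multiplet shapes are supported; arbitrary spin
  systems (e.g. true triplets or higher multiplets) must be approximated or
  added as new shape codes.
* The deconvolution assumes phased, baseline-flat input; strong residual
  baseline curvature biases areas.
* Variogram fitting with few sites is noisy, and the flat-vs-structure
  decision near the boundary is heuristic; borderline variables may
  alternate between kriging and RBF surfaces across reruns with different
  data.
* No anisotropy, no universal/co-kriging, no masking of interpolated
  surfaces to the field polygon.
* The kernel-weight, kriging and RBF solvers are dense; beyond a few
  thousand sites they would need sparse or local alternatives.
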