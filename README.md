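# geometab

Spatially resolved metabolomics from 1D ¹H-NMR profiles.

`geometab` is for analysts who ask not *what* a crop's metabolome looks like
but *where* it changes across a field. It implements, as a tested and
reusable R pipeline, the analysis chain used to map the metabolic expression
of durum wheat over precision-managed fields:

1. **NMR processing** — free induction decays are apodized (exponential,
   0.3 Hz), Fourier transformed, phase- and baseline-corrected, and the ppm
   axis is calibrated to the DSS reference at 0.015 ppm.
2. **Targeted quantification** — a catalog of annotated signals (compound,
   chemical shift σ, multiplet shape: `s`, `d`, `dd`, `5m`) is deconvolved
   as sums of tied Lorentzian components; the two built-in catalogs cover 21
   signals of wheat-shoot extracts and 20 of blooming-spike extracts,
   including the crowded 5.38–5.44 ppm polysaccharide cluster, which is fit
   jointly in one window.
3. **Metabolic indexes** — the site × metabolite matrix is standardized
   (z-scores, population σ) and collapsed to a per-site scalar
   MI_i = Σ_j w_j z_ij with three weighting schemes: *mean* (w_j = 1/N),
   *CoV* (w_j = CoV_j / Σ CoV_j, CoV = σ/μ on raw concentrations), and
   *PCA* (w = PC1 loadings).
4. **Geostatistics** — WGS84 → UTM projection (zone 34N by default,
   Krüger n⁶ series), empirical semivariograms
   γ̂(h) = Σ(z_i − z_j)²/2N(h) in 20 standard bins, weighted
   exponential-model fits γ(h) = c₀ + c(1 − e^(−h/ℓ)), ordinary kriging,
   thin-plate RBF interpolation (the fallback when the variogram is flat),
   global Moran's I with adaptive triangular-kernel weights (k = 7 nearest
   neighbours) and a permutation test, local Moran (LISA) with HH/LL/HL/LH
   cluster quadrants, and histogram/KDE/Q–Q diagnostics.
5. **Synthetic data** — Gaussian random fields with exponential covariance
   C(h) = sill·e^(−h/ℓ), spatially clustered bimodal mixtures, ~3 m GPS
   jitter, and synthetic FIDs built from the signal catalogs, so the entire
   pipeline can be exercised and validated without any external data.

Everything is driven either from the exported functions or end-to-end via
`runPipeline()`, which writes tables, interpolated surfaces and a JSON run
manifest from a single declarative config.

## Worked example

```r
library(geometab)

## 1) synthesize and quantify one wheat-shoot spectrum
catal <- signalCatalog("shoots")
set.seed(42)
amps <- runif(21, 0.5, 2)                      # true areas
fid  <- apodize(synthesizeFID(catal, amps), lbHz = 0.3)
spec <- calibrateSpectrum(transformSpectrum(fid))
q <- deconvolve(spec, catal)
head(q[, c("compound", "fitted_center_ppm", "fitted_fwhm_hz", "area")], 4)
#>   compound fitted_center_ppm fitted_fwhm_hz   area
#> 1      Val            0.9958          1.100 1.8728
#> 2      Ile            1.0139          1.100 1.9064
#> 3       U1            1.1119          1.102 0.9307
#> 4       U2            1.2528          1.101 1.7468

## 2) a spatially structured field, its variogram and Moran's I
fs  <- fieldSpec(nSites = 100, extentM = c(500, 200), corrLengthM = 100,
                 seed = 1)
pos <- samplePositions(fs)
xy  <- projectToUTM(pos$lat, pos$lon)
z   <- simulateGRF(xy, fs)
fitExponentialVariogram(empiricalVariogram(xy, z, nBins = 20))
#> VariogramModel (exponential): nugget=0.02491 sill=0.7294 length=79.73 m (effective range 239.2 m)
#>   19 nonempty bins
moransI(z, kernelWeights(xy, k = 7), nPerm = 999, seed = 1)
#> Moran's I = 0.4370 (E[I] = -0.0101), permutation p = 0.001 (999 perms)
```

The fitted centers reproduce the catalogued chemical shifts at their printed
4-decimal precision and the recovered areas match the synthesized ones to
within 0.5%; the simulated field's correlation length (truth 100 m) is
recovered by the variogram fit and its spatial structure is detected by the
permutation test.

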