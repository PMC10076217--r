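# panorf

Panoramic natural scenes are statistically anisotropic: luminance and
contrast rise from the dim ground to the bright sky, with an abrupt jump at
the horizon, so under constant photoreceptor noise the signal-to-noise
ratio (SNR) of retinal input varies with elevation.  `panorf` implements
the computational chain that links this structure to the retina-wide
organization of retinal ganglion cell (RGC) receptive fields (RFs), for
computational neuroscientists who want to generate the efficient-coding
predictions and validate the measurement pipeline on a fully controlled
synthetic retina.

The core model: a linear RF $\phi$ responding with $r_t = \phi^T s_t$ to
noisy stimulus patches is optimized to minimize

$$L(\phi) = \langle |r_t| \rangle_t + \lambda \sum_i \phi_i^2 d(i),
\qquad \lVert\phi\rVert = 1,$$

where $d(i)$ is the squared pixel distance to the peak-$|\phi|$ pixel and
$\lambda$ the locality strength — a sparse/predictive-coding cost whose
optima are centre-surround filters.  Sweeping the input noise variance and
the vertical SNR balance yields three predictions: relative surround
strength rises with SNR, centre size falls with SNR, and the surround
becomes vertically asymmetric where the SNR is vertically asymmetric
(i.e., at the horizon).

The measurement side mirrors a large-scale calcium-imaging experiment:
binary shifting white-noise checkerboards (100 µm checkers, 10 µm shifts,
6 Hz), calcium-triggered-average RF estimation with population
subtraction, [-1, 1] normalization, variance-peak localization, 1 mm
cropping, a strict 15 dB SNR filter, a constrained two-stage
difference-of-Gaussians (DoG) parametrization with centre/surround pixel
sets, and population statistics (six-bin dorsoventral profiles,
Kolmogorov–Smirnov tests, elevation/azimuth regression weights,
diagonal-covariance Gaussian-mixture clustering with BIC-elbow selection,
tiling index, saccade orientation tuning).  A synthetic retina with known
dorsoventral gradients makes every stage testable by parameter recovery.

## Worked example

```r
library(panorf)

# surrogate scenes and the elevation profile of stimulus power
scn <- run_scene_statistics(seed = 1, n_images = 100)
scn$power_ratio_top_bottom   # ~13: sky carries far more power than ground
scn$peak_asym_row            # 30 == horizon row: asymmetry peaks there

# one optimized receptive field at moderate noise
p    <- scene_params(horizon_step = 1,
                     luminance_gradient = function(e) rep(4, length(e)),
                     contrast_gradient  = function(e) rep(1, length(e)),
                     image_shape = c(60, 120))
imgs <- lapply(1:40, function(i) generate_panorama(p, seed = i))
raw  <- sample_patches(imgs, 5000, edge = 15, seed = 2)
ens  <- corrupt_patches(raw, noise_spec(sigma2 = 1, seed = 3))
rf   <- optimize_rf(ens, lam = 0.05, seed = 1, warn = FALSE)
matrix(rf$phi, 15)[7:9, 7:9]       # negative centre, positive annulus
characterize_model_rf(rf, radius = radius90(rf$phi, 15))$relative_surround
```

Running the numbered analyses end to end (each writes tables under
`results/`):

```sh
Rscript analysis/01_scene_statistics.R    # power/SNR/asymmetry profiles
Rscript analysis/02_theory_sweeps.R       # the three RF predictions
Rscript analysis/03_simulate_retina.R     # 500-cell ground-truth retina
Rscript analysis/04_map_and_fit.R         # map + DoG-fit the recording
Rscript analysis/05_population_trends.R   # bins, KS tests, regressions
Rscript analysis/06_clustering_and_saccades.R
```

`02_theory_sweeps.R` prints the seed-averaged sweep tables; at the default
conditions relative surround strength falls monotonically with noise
variance (about 0.97 → 0.25 over σ² = 1…64, i.e. rises with SNR) while
centre size rises (about 7 → 10 pixels), and the RF vertical asymmetry
rises from ≈0.07 (symmetric input) to ≈0.91 as the bottom-half scaling
drops to 0.4.  `04_map_and_fit.R` reports per-cell recovery correlations
between measured and true metrics (about 0.9 for relative surround, 0.85
for vertical asymmetry, 0.99 rank correlation for centre size) and
`05_population_trends.R` the dorsoventral KS p-values and regression
weights, with the elevation weight dominating the azimuth weight for all
three metrics.

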