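# gradfit3d

Fast 3D sub-pixel localization of single fluorescent emitters in
astigmatism-based microscopy (3D STORM/PALM, single-particle tracking),
using a closed-form **gradient-direction fit** instead of iterative
Gaussian fitting.

## Who this is for and what it does

In astigmatic localization microscopy a cylindrical lens makes the PSF
elliptical, with the ellipticity encoding axial position. Each detected
emitter must then be localized in x, y **and** z from one small pixel
patch. The standard tools — non-linear least squares (NLLS) or Poisson
maximum-likelihood (MLE) fits of an elliptical Gaussian — iterate; this
package recovers the same three quantities in a **single 3×3 linear
solve**.

The PSF model is the pixel-integrated elliptical Gaussian with centre
(x_c, y_c), widths (w_x, w_y), photon count N and constant background b;
ellipticity is e = (w_y/w_x)². The key observation is that the gradient of
such a PSF at position (m, n) points along −(e·(m−x_c), n−y_c). The fit
measures the image-gradient field of a 15×15 ROI with a smoothed
derivative kernel pair, and minimises the weighted squared sine of the
angle between each measured gradient and the model direction,

    D(x_c, y_c, e) = Σ_k W_k · sin²θ_k ,
    sin θ_k = [g_x,k (n_k − y_c) − e · g_y,k (m_k − x_c)] / (|g_k||v_k|),

with weights W_k = |g_k|²/Ī_k (inverse relative direction variance under
Poisson noise) restricted to a 4 px central area. Freezing |v_k| and W_k at
a centroid pre-estimate makes D quadratic in (e, e·x_c, y_c), so the
minimiser is closed-form. z is decoded from the fitted ellipticity via a
quartic z–e calibration curve, inverted consistently with the gradient
operator's known smoothing.

The package also ships the matching simulator (Poisson shot noise,
calibration-derived widths), an axial calibration module (quartic fits,
width-difference / width-approximation / ellipticity decoders), reference
localizers (centroid, NLLS, MLE), exact Cramér–Rao bounds, an MSD utility
for tracking, a benchmark harness, and a small CLI
(`inst/cli/gradfit3d`: simulate / calibrate / localize / track /
benchmark).

## Worked example

Simulate five frames of a single emitter at z = +200 nm under typical
dSTORM conditions (5000 photons, 100 background photons/pixel, 160 nm
pixels), then detect and localize:

```r
library(gradfit3d)

cal   <- default_calibration()                      # synthetic astigmatic curve
stack <- simulate_stack(5, camera_model(background = 100), cal,
                        z_nm = 200, photons = 5000, seed = 7)
localize_stack(stack, cal)
#> # A tibble: 5 × 8
#>   frame  x_nm  y_nm  z_nm ellipticity photons background flags
#>   <int> <dbl> <dbl> <dbl>       <dbl>   <dbl>      <dbl> <chr>
#> 1     1 2638. 2545.  205.        1.65   5652.       99.8 ""
#> 2     2 2501. 2494.  194.        1.61   5671.       98.3 ""
#> 3     3 2515. 2594.  182.        1.57   5510.       99.8 ""
#> 4     4 2530. 2616.  189.        1.60   5774.       98.4 ""
#> 5     5 2514. 2546.  161.        1.50   5410.      101.  ""
```

Coordinates are nanometres in the frame (the emitter sits near pixel
(16, 16) ≈ 2560 nm); `z_nm` scatters around the true +200 nm; the
ellipticity column is the fitted field ellipticity the z decoder consumed.

A small precision study comparing the gradient fit with a centroid-class
localizer (200 frames per depth):

```r
rep <- run_precision_study(
  precision_protocol(z_grid = c(-200, 0, 200), frames_per_z = 200),
  algorithms = c("gradient", "centroid_wd"), seed = 1)
rep[, c("algorithm", "z_nm", "std_x", "std_y", "std_z")]
#>     algorithm z_nm std_x std_y std_z
#> 1    gradient -200  7.67  5.36  21.2
#> 2 centroid_wd -200 14.32 13.40  83.7
#> 3    gradient    0  5.54  5.67  15.3
#> 4 centroid_wd    0 13.71 14.21  58.1
#> 5    gradient  200  5.01  7.17  21.7
#> 6 centroid_wd  200 14.89 14.95  75.6
```

`std_*` is the localization precision in nm (standard deviation of the
localization error per axis); the gradient fit is 2–4× more precise than
the single-pass centroid in every axis, and sits within ~10 % of the
Cramér–Rao bound (`crlb()`) laterally. `autoplot(rep)` draws the
precision-vs-depth curves; `autoplot(cal)` the calibration curves.

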