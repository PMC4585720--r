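## Shared fixtures: all inputs are generated in code at test time.

## noise-free integrated PSF ROI (independent construction is in the
## oracles inside each test; this helper uses the package itself)
make_roi <- function(x_c = 7, y_c = 7, w_x = 1.4, w_y = 1.4, photons = 5000,
                     background = 20, size = 15L, frame_index = 1L,
                     noisy = FALSE, seed = 1L) {
  cam <- camera_model(background = background,
                      frame_shape = c(size, size))
  mu <- integrated_psf(emitter_truth(x_c, y_c, w_x, w_y, photons), cam)
  px <- if (noisy) {
    withr::with_seed(seed, matrix(rpois(length(mu), mu), size, size))
  } else {
    mu
  }
  spot_roi(px, origin = c(0, 0), frame_index = frame_index)
}

## synthetic bead-stack measurement table for calibration tests, generated
## from the standard defocus hyperbola
make_width_table <- function(z = seq(-400, 400, by = 100), w0 = 1.3,
                             d = 400, gamma = 200, replicates = 1,
                             noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    tidyr::expand_grid(z_nm = z, rep = seq_len(replicates)) |>
      dplyr::mutate(
        wx_px = w0 * sqrt(1 + ((z_nm - gamma) / d)^2) +
          rnorm(dplyr::n(), sd = noise_sd),
        wy_px = w0 * sqrt(1 + ((z_nm + gamma) / d)^2) +
          rnorm(dplyr::n(), sd = noise_sd))
  })
}

## quartic evaluation used by test oracles (kept separate from the package
## internals on purpose)
quartic_at <- function(coeff, z) {
  coeff[1] + coeff[2] * z + coeff[3] * z^2 + coeff[4] * z^3 + coeff[5] * z^4
}
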