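#' Ground-truth parameters of a single emitter
#'
#' Bundles the parameters of one fluorophore: lateral centre, Gaussian PSF
#' widths, total photon count and (optionally) the axial position the widths
#' were derived from.
#'
#' @param x_c,y_c Lateral centre in pixels (0-based, pixel centres at
#'   integers).
#' @param w_x,w_y Gaussian widths (standard deviations) of the PSF in pixels.
#' @param photons Total emitted photon count `N` (must be >= 0; 0 gives a
#'   dark emitter).
#' @param z_nm Optional axial position in nm. Informational; when an emitter
#'   is built from a calibration curve the widths are derived from this.
#' @return An object of class `emitter_truth`.
#' @export
emitter_truth <- function(x_c, y_c, w_x, w_y, photons, z_nm = NA_real_) {
  if (w_x <= 0 || w_y <= 0) stop_invalid("PSF widths must be positive.")
  if (photons < 0) stop_invalid("Photon count must be non-negative.")
  structure(
    list(x_c = x_c, y_c = y_c, w_x = w_x, w_y = w_y,
         photons = photons, z_nm = z_nm),
    class = "emitter_truth"
  )
}

#' @export
print.emitter_truth <- function(x, ...) {
  cat(sprintf(
    "<emitter_truth> centre (%.3f, %.3f) px, widths (%.3f, %.3f) px, %g photons",
    x$x_c, x$y_c, x$w_x, x$w_y, x$photons))
  if (!is.na(x$z_nm)) cat(sprintf(", z = %g nm", x$z_nm))
  cat("\n")
  invisible(x)
}

#' Camera and frame geometry
#'
#' @param pixel_size_nm Physical pixel size in nm (default 160 nm).
#' @param background Constant background level in photons per pixel.
#' @param frame_shape Integer vector `c(rows, cols)` in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 160, background = 100,
                         frame_shape = c(33L, 33L)) {
  if (pixel_size_nm <= 0) stop_invalid("pixel_size_nm must be positive.")
  if (background < 0) stop_invalid("background must be non-negative.")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 1L)) {
    stop_invalid("frame_shape must be two positive integers.")
  }
  structure(
    list(pixel_size_nm = pixel_size_nm, background = background,
         frame_shape = frame_shape),
    class = "camera_model"
  )
}

## 1D pixel-integrated Gaussian profile over pixels 0..(n-1)
pixel_profile <- function(centre, width, n) {
  diff(pnorm(seq(-0.5, n - 0.5, by = 1), mean = centre, sd = width))
}

#' Noise-free integrated elliptical-Gaussian image
#'
#' Each pixel holds the exact integral of the unit-normalised elliptical
#' Gaussian density over the pixel area, times the photon count, plus the
#' camera background.  The integral uses the separable error-function
#' difference form, so it is exact up to floating point.
#'
#' @param truth An [emitter_truth()].
#' @param camera A [camera_model()].
#' @return A numeric matrix of expected photon counts (no noise).
#' @export
integrated_psf <- function(truth, camera) {
  stopifnot(inherits(truth, "emitter_truth"), inherits(camera, "camera_model"))
  if (truth$photons <= 0) {
    stop_invalid("integrated_psf() requires a positive photon count.")
  }
  nr <- camera$frame_shape[1]
  nc <- camera$frame_shape[2]
  px <- pixel_profile(truth$x_c, truth$w_x, nr)
  py <- pixel_profile(truth$y_c, truth$w_y, nc)
  truth$photons * outer(px, py) + camera$background
}

#' Exact spatial gradient of the continuous PSF
#'
#' Evaluates the analytic gradient of the continuous elliptical-Gaussian
#' density \eqn{I(m, n)} (photon-normalised, no background) at arbitrary
#' continuous coordinates.  The gradient direction at any point is
#' proportional to \eqn{-(e (m - x_c), (n - y_c))} up to a positive scalar,
#' with \eqn{e = (w_y/w_x)^2}; this elliptical-convergence property is what
#' the gradient fit exploits.
#'
#' @param truth An [emitter_truth()].
#' @param coords Two-column matrix (or coercible) of `(m, n)` positions.
#' @return A matrix with columns `gx`, `gy`, one row per coordinate.
#' @export
psf_gradient <- function(truth, coords) {
  stopifnot(inherits(truth, "emitter_truth"))
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 2)
  dm <- coords[, 1] - truth$x_c
  dn <- coords[, 2] - truth$y_c
  dens <- truth$photons / (2 * pi * truth$w_x * truth$w_y) *
    exp(-dm^2 / (2 * truth$w_x^2) - dn^2 / (2 * truth$w_y^2))
  cbind(gx = -dens * dm / truth$w_x^2,
        gy = -dens * dn / truth$w_y^2)
}

#' Simulate a stack of noisy single-emitter frames
#'
#' Generates `n_frames` independent Poisson realisations of the integrated
#' elliptical-Gaussian PSF plus constant background, following the standard
#' numerical evaluation protocol for astigmatic localization algorithms:
#' one emitter per frame, its sub-pixel position drawn uniformly within the
#' central pixel, widths taken from the axial calibration at the requested
#' depth.
#'
#' @param n_frames Number of frames to generate.
#' @param camera A [camera_model()].
#' @param calibration An [astig_calibration] used to derive widths from
#'   `z_nm`. Ignored when `truth_fun` is supplied.
#' @param z_nm Axial position of the emitter in nm.
#' @param photons Total photons per emitter (default 5000).
#' @param position Either `NULL` (uniform in the central pixel) or a fixed
#'   `c(x, y)` centre in pixels.
#' @param truth_fun Optional generator `function(frame_index)` returning an
#'   [emitter_truth()]; overrides `z_nm`/`photons`/`position`.
#' @param seed Integer RNG seed. The same seed reproduces the stack
#'   bit-for-bit.
#' @return A `frame_stack`: list of frames, ground-truth table, seed, camera.
#' @export
simulate_stack <- function(n_frames, camera = camera_model(),
                           calibration = default_calibration(),
                           z_nm = 0, photons = 5000, position = NULL,
                           truth_fun = NULL, seed = 1L) {
  if (n_frames < 1) stop_invalid("n_frames must be >= 1.")
  nr <- camera$frame_shape[1]
  nc <- camera$frame_shape[2]
  centre <- c((nr - 1) %/% 2, (nc - 1) %/% 2)
  if (is.null(truth_fun)) {
    w <- eval_calibration(calibration, z_nm)
    truth_fun <- function(i) {
      pos <- if (is.null(position)) centre + runif(2, -0.5, 0.5) else position
      emitter_truth(pos[1], pos[2], w$w_x, w$w_y, photons, z_nm = z_nm)
    }
  }
  withr::with_seed(seed, {
    truths <- lapply(seq_len(n_frames), truth_fun)
    frames <- lapply(truths, function(tr) {
      mu <- if (tr$photons > 0) {
        integrated_psf(tr, camera)
      } else {
        matrix(camera$background, nr, nc)
      }
      matrix(rpois(length(mu), mu), nr, nc)
    })
    truth <- tibble(
      frame = seq_len(n_frames),
      x_px = vapply(truths, `[[`, numeric(1), "x_c"),
      y_px = vapply(truths, `[[`, numeric(1), "y_c"),
      z_nm = vapply(truths, `[[`, numeric(1), "z_nm"),
      photons = vapply(truths, `[[`, numeric(1), "photons"),
      background = camera$background
    )
    structure(
      list(frames = frames, truth = truth, seed = seed, camera = camera),
      class = "frame_stack"
    )
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px, seed %s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              format(x$seed)))
  invisible(x)
}
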