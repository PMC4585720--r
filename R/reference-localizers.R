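## Reference localizers for benchmarking and calibration building:
## iterative elliptical-Gaussian fits (least squares and Poisson maximum
## likelihood) and a single-pass moment ("centroid-WD") localizer of the
## QuickPALM precision class.

## model: mu(i, j) = N * px_i * py_j + b  over an nr x nc grid,
## p = (x, y, wx, wy, N, b)
psf_model_mu <- function(p, nr, nc) {
  p[5] * outer(pixel_profile(p[1], p[3], nr),
               pixel_profile(p[2], p[4], nc)) + p[6]
}

## analytic Jacobian d mu / d p, returned as (nr*nc) x 6
psf_model_jac <- function(p, nr, nc) {
  x <- p[1]; y <- p[2]; wx <- p[3]; wy <- p[4]; n_ph <- p[5]
  bx <- seq(-0.5, nr - 0.5, by = 1)
  by <- seq(-0.5, nc - 0.5, by = 1)
  hx <- (bx - x) / wx; hy <- (by - y) / wy
  px <- diff(pnorm(hx)); py <- diff(pnorm(hy))
  dx <- -diff(dnorm(hx)) / wx            # d px / d x
  dy <- -diff(dnorm(hy)) / wy
  dwx <- -diff(dnorm(hx) * hx) / wx      # d px / d wx
  dwy <- -diff(dnorm(hy) * hy) / wy
  cbind(
    x = n_ph * as.vector(outer(dx, py)),
    y = n_ph * as.vector(outer(px, dy)),
    wx = n_ph * as.vector(outer(dwx, py)),
    wy = n_ph * as.vector(outer(px, dwy)),
    N = as.vector(outer(px, py)),
    b = 1
  )
}

## shared initialisation from the centroid stage
gaussian_init <- function(roi) {
  init <- centroid_init(roi)
  c(x = init$x0, y = init$y0,
    wx = sqrt(max(init$var_x - 1 / 12, 0.25)),
    wy = sqrt(max(init$var_y - 1 / 12, 0.25)),
    N = max(init$photons, 1),
    b = max(init$background, 0))
}

new_psf_fit <- function(p, converged, iterations, objective, method) {
  structure(
    list(x_c = p[1], y_c = p[2], w_x = p[3], w_y = p[4],
         photons = p[5], background = p[6],
         converged = converged, iterations = iterations,
         objective = objective, method = method),
    class = "psf_fit"
  )
}

#' @export
print.psf_fit <- function(x, ...) {
  cat(sprintf(
    "<psf_fit:%s> centre (%.4f, %.4f) px, widths (%.4f, %.4f) px, N = %.1f, b = %.2f (%s, %d it.)\n",
    x$method, x$x_c, x$y_c, x$w_x, x$w_y, x$photons, x$background,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @method tidy psf_fit
#' @export
tidy.psf_fit <- function(x, ...) {
  tibble(term = c("x_c", "y_c", "w_x", "w_y", "photons", "background"),
         estimate = c(x$x_c, x$y_c, x$w_x, x$w_y, x$photons, x$background))
}

#' @method glance psf_fit
#' @export
glance.psf_fit <- function(x, ...) {
  tibble(converged = x$converged, iterations = x$iterations,
         objective = x$objective, method = x$method)
}

#' Non-linear least squares elliptical-Gaussian fit
#'
#' Fits the 6-parameter integrated elliptical Gaussian plus constant
#' background to an ROI by damped least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) with an analytic Jacobian, to a relative tolerance of
#' 1e-6 or 100 iterations.
#'
#' @param roi A [spot_roi()].
#' @param init Optional named parameter vector `(x, y, wx, wy, N, b)`;
#'   defaults to the centroid-stage initialisation.
#' @return A `psf_fit`.
#' @export
fit_psf_nlls <- function(roi, init = NULL) {
  stopifnot(inherits(roi, "spot_roi"))
  a <- roi$pixels
  nr <- nrow(a); nc <- ncol(a)
  p0 <- init %||% gaussian_init(roi)
  res <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) as.vector(psf_model_mu(p, nr, nc)) - as.vector(a),
    jac = function(p) psf_model_jac(p, nr, nc),
    lower = c(-1, -1, 0.2, 0.2, 1, 0),
    upper = c(nr, nc, nr, nc, Inf, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-6, ptol = 1e-6,
                                         maxiter = 100)
  )
  new_psf_fit(unname(res$par), res$info %in% 1:4, res$niter,
              res$deviance, "nlls")
}

#' Poisson maximum-likelihood elliptical-Gaussian fit
#'
#' Maximises the Poisson log-likelihood of the same 6-parameter model
#' (L-BFGS-B with the analytic score), to a projected-gradient tolerance
#' consistent with 1e-6 relative or 200 iterations.  Requires
#' photon-calibrated pixel values for the Poisson model to be meaningful.
#'
#' @inheritParams fit_psf_nlls
#' @return A `psf_fit` with `objective` the negative log-likelihood.
#' @export
fit_psf_mle <- function(roi, init = NULL) {
  stopifnot(inherits(roi, "spot_roi"))
  a <- as.vector(roi$pixels)
  nr <- nrow(roi$pixels); nc <- ncol(roi$pixels)
  p0 <- init %||% gaussian_init(roi)
  nll <- function(p) {
    mu <- pmax(as.vector(psf_model_mu(p, nr, nc)), 1e-12)
    sum(mu - a * log(mu))
  }
  grad <- function(p) {
    mu <- pmax(as.vector(psf_model_mu(p, nr, nc)), 1e-12)
    drop(crossprod(psf_model_jac(p, nr, nc), 1 - a / mu))
  }
  res <- optim(p0, nll, grad, method = "L-BFGS-B",
               lower = c(-1, -1, 0.2, 0.2, 1, 1e-6),
               upper = c(nr, nc, nr, nc, Inf, Inf),
               control = list(maxit = 200, factr = 1e4))
  new_psf_fit(unname(res$par), res$convergence == 0,
              res$counts[["function"]], res$value, "mle")
}

#' Single-pass moment localizer (centroid-WD, QuickPALM-like)
#'
#' A reference stand-in for the single-iteration centroid precision class:
#' centre from the intensity-weighted centroid, per-axis widths from second
#' central moments, z decoded from the width-difference calibration curve.
#' It is not a re-implementation of any particular published tool.
#'
#' @param roi A [spot_roi()].
#' @param curve An `astig_calibration`, or `NULL` for 2D.
#' @param pixel_size_nm Pixel size in nm.
#' @return One-row localization tibble (same schema as [localize_roi()]).
#' @export
localize_centroid_wd <- function(roi, curve = NULL, pixel_size_nm = 160) {
  init <- centroid_init(roi)
  wx <- sqrt(max(init$var_x - 1 / 12, 0.0025))
  wy <- sqrt(max(init$var_y - 1 / 12, 0.0025))
  flags <- character(0)
  z <- NA_real_
  if (!is.null(curve)) {
    zd <- z_from_widths_wd(curve, wx, wy)
    z <- zd$z_nm
    if (zd$range_clipped) flags <- c(flags, "range_clipped")
  }
  tibble(
    frame = roi$frame_index,
    x_nm = (roi$origin[1] + init$x0) * pixel_size_nm,
    y_nm = (roi$origin[2] + init$y0) * pixel_size_nm,
    z_nm = z,
    ellipticity = ellipticity_from_widths(wx, wy),
    photons = init$photons,
    background = init$background,
    flags = paste(flags, collapse = ";")
  )
}
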