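#' Ellipticity convention
#'
#' The package measures the asymmetry of an astigmatic PSF as the squared
#' width ratio \eqn{e = (w_y / w_x)^2}.  A single exponent constant is shared
#' by the simulator, the calibration module and the gradient fitter so that
#' the forward definition and every inversion are always consistent.  With
#' this convention the exact gradient direction of an elliptical Gaussian at
#' a point \eqn{(m, n)} is proportional to \eqn{(e (m - x_c), (n - y_c))},
#' which is what makes the closed-form fit linear in \eqn{(e, e x_c, y_c)}.
#'
#' @return `ellipticity_exponent()` returns the integer exponent (2).
#' @export
ellipticity_exponent <- function() 2L

#' @param w_x,w_y Gaussian PSF widths (standard deviations) in pixels.
#' @return `ellipticity_from_widths()` returns \eqn{(w_y/w_x)^2}.
#' @rdname ellipticity_exponent
#' @export
ellipticity_from_widths <- function(w_x, w_y) {
  if (any(w_x <= 0) || any(w_y <= 0)) {
    stop_invalid("PSF widths must be positive.")
  }
  (w_y / w_x)^ellipticity_exponent()
}
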