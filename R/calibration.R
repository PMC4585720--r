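## Axial (z) calibration: quartic polynomials for w_x(z), w_y(z) and
## ellipticity e(z), plus their inversions.  Coefficients are stored lowest
## order first, widths in pixels, z in nanometres.

poly_eval <- function(coeff, z) {
  out <- 0
  for (k in rev(seq_along(coeff))) out <- out * z + coeff[k]
  out
}

## re-express p(z) as q(t) with t = z - z0, i.e. q(t) = p(t + z0)
poly_shift <- function(coeff, z0) {
  n <- length(coeff)
  out <- numeric(n)
  for (k in seq_len(n)) {          # term coeff[k] * (t + z0)^(k-1)
    for (j in seq_len(k)) {
      out[j] <- out[j] + coeff[k] * choose(k - 1, j - 1) * z0^(k - j)
    }
  }
  out
}

fit_quartic <- function(z, y) {
  unname(coef(lm(y ~ poly(z, 4, raw = TRUE))))
}

## maximal interval around z = 0 on which the quartic is strictly monotone:
## trim at the real roots of the derivative
monotone_span <- function(coeff, z_min, z_max) {
  dcoeff <- coeff[-1] * seq_len(length(coeff) - 1)
  r <- polyroot(dcoeff)
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  lo <- z_min
  hi <- z_max
  for (x in r) {
    if (x > lo && x < 0) lo <- x
    if (x < hi && x >= 0) hi <- x
  }
  c(lo, hi)
}

#' Fit an axial calibration from bead-stack width measurements
#'
#' Takes per-position width measurements of a single bead imaged through the
#' astigmatic optics, averages replicates at each axial position, and fits
#' 4th-order (quartic) polynomials to the averaged \eqn{w_x(z)},
#' \eqn{w_y(z)} and to the ellipticity \eqn{e(z) = (w_y/w_x)^2} computed
#' from the averaged widths.  The axial zero position is defined as the
#' position with minimal width difference \eqn{|w_x - w_y|}, located by a
#' dense 0.1 nm scan of the fitted width polynomials; all curves are then
#' re-expressed with that point as z = 0.
#'
#' The ellipticity curve must be strictly monotone to be invertible.  The
#' averaged measurements are required to be strictly monotone in e; the
#' validity range of the stored curve is additionally trimmed to the maximal
#' span around z = 0 on which the fitted quartic itself is monotone (a
#' quartic fitted to a flattening curve can turn over just inside the
#' scanned range).
#'
#' @param data Data frame with columns `z_nm`, `wx_px`, `wy_px`; replicate
#'   measurements at the same `z_nm` occupy multiple rows.
#' @param pixel_size_nm Pixel size recorded in the calibration (metadata).
#' @return An object of class `astig_calibration`.
#' @export
fit_calibration <- function(data, pixel_size_nm = 160) {
  req <- c("z_nm", "wx_px", "wy_px")
  if (!all(req %in% names(data))) {
    stop_invalid(paste("Calibration data needs columns:",
                       paste(req, collapse = ", ")))
  }
  means <- data |>
    dplyr::group_by(.data$z_nm) |>
    dplyr::summarise(wx = mean(.data$wx_px), wy = mean(.data$wy_px),
                     .groups = "drop") |>
    dplyr::arrange(.data$z_nm)
  if (nrow(means) < 5) {
    stop_invalid("At least 5 distinct z positions are required for a quartic fit.")
  }
  if (any(means$wx <= 0) || any(means$wy <= 0)) {
    stop_invalid("Averaged widths must be positive.")
  }
  e_meas <- ellipticity_from_widths(means$wx, means$wy)
  de <- diff(e_meas)
  if (!(all(de > 0) || all(de < 0))) {
    bad <- which(sign(de) != sign(de[1]))[1]
    abort(
      sprintf(
        "Ellipticity is not monotone in z: direction reverses between %g nm and %g nm.",
        means$z_nm[bad], means$z_nm[bad + 1]),
      class = "gradfit3d_calibration_rejected"
    )
  }

  coeff_wx <- fit_quartic(means$z_nm, means$wx)
  coeff_wy <- fit_quartic(means$z_nm, means$wy)
  coeff_e  <- fit_quartic(means$z_nm, e_meas)

  ## zero position: dense 0.1 nm scan of |w_x - w_y| on the fitted curves
  zg <- seq(min(means$z_nm), max(means$z_nm), by = 0.1)
  z_zero <- zg[which.min(abs(poly_eval(coeff_wx, zg) - poly_eval(coeff_wy, zg)))]

  coeff_wx <- poly_shift(coeff_wx, z_zero)
  coeff_wy <- poly_shift(coeff_wy, z_zero)
  coeff_e  <- poly_shift(coeff_e, z_zero)
  z_min <- min(means$z_nm) - z_zero
  z_max <- max(means$z_nm) - z_zero

  span <- monotone_span(coeff_e, z_min, z_max)
  if (span[1] > z_min + 1e-9 || span[2] < z_max - 1e-9) {
    warn(sprintf(
      "Fitted ellipticity quartic is monotone only on [%.1f, %.1f] nm; validity range trimmed.",
      span[1], span[2]))
  }
  new_calibration(coeff_wx, coeff_wy, coeff_e, span[1], span[2], z_zero,
                  pixel_size_nm,
                  meta = list(n_positions = nrow(means),
                              n_measurements = nrow(data)))
}

new_calibration <- function(coeff_wx, coeff_wy, coeff_e, z_min, z_max,
                            z_zero, pixel_size_nm, meta = list()) {
  obj <- structure(
    list(coeff_wx = as.numeric(coeff_wx), coeff_wy = as.numeric(coeff_wy),
         coeff_e = as.numeric(coeff_e), z_min = z_min, z_max = z_max,
         z_zero = z_zero, pixel_size_nm = pixel_size_nm, meta = meta),
    class = "astig_calibration"
  )
  zz <- seq(z_min, z_max, length.out = 101)
  if (any(poly_eval(coeff_wx, zz) <= 0) || any(poly_eval(coeff_wy, zz) <= 0)) {
    abort("Width polynomials are not positive over the validity range.",
          class = "gradfit3d_calibration_rejected")
  }
  obj
}

#' Evaluate a calibration curve
#'
#' @param curve An `astig_calibration`.
#' @param z_nm Axial positions in nm (vectorised).
#' @return A tibble with columns `z_nm`, `w_x`, `w_y`, `e`.
#' @export
eval_calibration <- function(curve, z_nm) {
  stopifnot(inherits(curve, "astig_calibration"))
  tibble(z_nm = z_nm,
         w_x = poly_eval(curve$coeff_wx, z_nm),
         w_y = poly_eval(curve$coeff_wy, z_nm),
         e = poly_eval(curve$coeff_e, z_nm))
}

## bracketed bisection on a monotone polynomial; values outside the curve's
## range are clamped to the nearer endpoint and flagged
invert_monotone <- function(coeff, targets, z_min, z_max, tol = 1e-4) {
  lo_val <- poly_eval(coeff, z_min)
  hi_val <- poly_eval(coeff, z_max)
  increasing <- hi_val > lo_val
  rng <- range(lo_val, hi_val)
  z <- numeric(length(targets))
  clipped <- logical(length(targets))
  for (i in seq_along(targets)) {
    v <- targets[i]
    if (v <= rng[1] || v >= rng[2]) {
      clipped[i] <- TRUE
      at_low <- (v <= rng[1])
      z[i] <- if (at_low == increasing) z_min else z_max
      ## exact endpoint hit is not really a clip
      if (v == rng[1] || v == rng[2]) clipped[i] <- FALSE
    } else {
      z[i] <- uniroot(function(zz) poly_eval(coeff, zz) - v,
                      lower = z_min, upper = z_max, tol = tol)$root
    }
  }
  tibble(z_nm = z, range_clipped = clipped)
}

#' Decode axial position from ellipticity
#'
#' Inverts the monotone quartic z-ellipticity calibration curve by
#' bracketing and bisection.  Ellipticity values outside the curve's range
#' clamp to the nearer endpoint and are flagged, never extrapolated: a
#' quartic diverges quickly outside its fitted support.
#'
#' @param curve An `astig_calibration`.
#' @param e_hat Measured ellipticity value(s), \eqn{(w_y/w_x)^2} convention.
#' @return A tibble with columns `z_nm` and `range_clipped`.
#' @export
z_from_ellipticity <- function(curve, e_hat) {
  stopifnot(inherits(curve, "astig_calibration"))
  if (any(!is.finite(e_hat)) || any(e_hat <= 0)) {
    stop_invalid("Ellipticity must be finite and positive.")
  }
  invert_monotone(curve$coeff_e, e_hat, curve$z_min, curve$z_max)
}

#' Decode axial position from widths (width-difference scheme)
#'
#' Looks up z on the quartic fitted to the width difference
#' \eqn{w_y(z) - w_x(z)}, the decoder used by width-difference calibrated
#' Gaussian fitting.
#'
#' @param curve An `astig_calibration`.
#' @param wx_hat,wy_hat Fitted widths in pixels (vectorised).
#' @return A tibble with columns `z_nm` and `range_clipped`.
#' @export
z_from_widths_wd <- function(curve, wx_hat, wy_hat) {
  stopifnot(inherits(curve, "astig_calibration"))
  dcoeff <- curve$coeff_wy - curve$coeff_wx
  span <- monotone_span(dcoeff, curve$z_min, curve$z_max)
  invert_monotone(dcoeff, wy_hat - wx_hat, span[1], span[2])
}

#' Decode axial position from widths (width-approximation scheme)
#'
#' Finds the z minimising the squared distance between the measured width
#' pair and the two width calibration curves,
#' \eqn{(\hat w_x - w_x(z))^2 + (\hat w_y - w_y(z))^2}, by a dense 1 nm grid
#' scan followed by local refinement.
#'
#' @inheritParams z_from_widths_wd
#' @return A tibble with columns `z_nm` and `range_clipped`.
#' @export
z_from_widths_wa <- function(curve, wx_hat, wy_hat) {
  stopifnot(inherits(curve, "astig_calibration"))
  zg <- seq(curve$z_min, curve$z_max, by = 1)
  wxg <- poly_eval(curve$coeff_wx, zg)
  wyg <- poly_eval(curve$coeff_wy, zg)
  n <- max(length(wx_hat), length(wy_hat))
  wx_hat <- rep_len(wx_hat, n)
  wy_hat <- rep_len(wy_hat, n)
  z <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (wx_hat[i] - wxg)^2 + (wy_hat[i] - wyg)^2
    k <- which.min(d2)
    lo <- zg[max(1, k - 1)]
    hi <- zg[min(length(zg), k + 1)]
    obj <- function(zz) {
      (wx_hat[i] - poly_eval(curve$coeff_wx, zz))^2 +
        (wy_hat[i] - poly_eval(curve$coeff_wy, zz))^2
    }
    z[i] <- optimize(obj, lower = lo, upper = hi, tol = 1e-3)$minimum
    clipped[i] <- (k == 1L || k == length(zg))
    if (clipped[i]) z[i] <- zg[k]
  }
  tibble(z_nm = z, range_clipped = clipped)
}

#' Decode axial position from an operator-field ellipticity
#'
#' A finite-support gradient operator measures the ellipticity of the
#' operator-blurred PSF, \eqn{e_b(z) = (w_y(z)^2 + s^2)/(w_x(z)^2 + s^2)}
#' with \eqn{s^2} the operator's known isotropic blur variance.  Decoding
#' the measured field ellipticity against this forward-blurred curve keeps
#' the estimate consistent (median-unbiased) without the noise
#' amplification of de-blurring each fit individually.  Inversion is by
#' dense 1 nm scan of the blurred curve on its monotone span around z = 0,
#' refined by bisection; out-of-range values clamp and flag.
#'
#' @param curve An `astig_calibration`.
#' @param e_hat Measured field ellipticity value(s).
#' @param blur_var Operator blur variance in px^2 (`blur_var` element of
#'   [gradient_operators()]).
#' @return A tibble with columns `z_nm` and `range_clipped`.
#' @export
z_from_field_ellipticity <- function(curve, e_hat, blur_var) {
  stopifnot(inherits(curve, "astig_calibration"))
  if (any(!is.finite(e_hat)) || any(e_hat <= 0)) {
    stop_invalid("Ellipticity must be finite and positive.")
  }
  g <- field_curve_grid(curve, blur_var)
  ## orient the table so the lookup ellipticity is increasing
  eb <- if (g$increasing) g$ebg else rev(g$ebg)
  zz <- if (g$increasing) g$zg else rev(g$zg)
  n <- length(eb)
  v <- pmin(pmax(e_hat, eb[1]), eb[n])
  clipped <- e_hat < eb[1] | e_hat > eb[n]
  k <- pmin(pmax(findInterval(v, eb), 1L), n - 1L)
  frac <- (v - eb[k]) / (eb[k + 1L] - eb[k])
  tibble::new_tibble(list(z_nm = zz[k] + frac * (zz[k + 1L] - zz[k]),
                          range_clipped = clipped),
                     nrow = length(v))
}

## memoised 0.1 nm lookup table of the operator-blurred ellipticity curve,
## trimmed to its monotone span around z = 0
field_curve_grid <- function(curve, blur_var) {
  ## fast path: the vast majority of calls reuse the previous curve
  if (!is.null(the$fieldgrid_last) &&
      identical(the$fieldgrid_last$curve[1:6], curve[1:6]) &&
      identical(the$fieldgrid_last$blur_var, blur_var)) {
    return(the$fieldgrid_last$grid)
  }
  key <- paste0("fieldgrid_",
                paste(format(c(curve$coeff_wx, curve$coeff_wy,
                               curve$z_min, curve$z_max, blur_var),
                             digits = 17), collapse = ","))
  if (!is.null(the[[key]])) {
    the$fieldgrid_last <- list(curve = curve, blur_var = blur_var,
                               grid = the[[key]])
    return(the[[key]])
  }
  zg <- seq(curve$z_min, curve$z_max, by = 0.1)
  ebg <- (poly_eval(curve$coeff_wy, zg)^2 + blur_var) /
    (poly_eval(curve$coeff_wx, zg)^2 + blur_var)
  d <- diff(ebg)
  i0 <- which.min(abs(zg))
  s0 <- sign(d[min(i0, length(d))])
  lo <- 1L
  for (i in seq(min(i0, length(d)), 1L)) {
    if (sign(d[i]) != s0) { lo <- i + 1L; break }
  }
  hi <- length(zg)
  for (i in seq(min(i0, length(d)), length(d))) {
    if (sign(d[i]) != s0) { hi <- i; break }
  }
  out <- list(zg = zg[lo:hi], ebg = ebg[lo:hi],
              increasing = ebg[hi] > ebg[lo])
  the[[key]] <- out
  the$fieldgrid_last <- list(curve = curve, blur_var = blur_var, grid = out)
  out
}

## cache for the default synthetic calibration
the <- new.env(parent = emptyenv())

#' Default synthetic astigmatic calibration
#'
#' A representative cylindrical-lens calibration used by the simulator and
#' the benchmark when no measured bead calibration is supplied.  Widths
#' follow the standard defocus hyperbola
#' \eqn{w(z) = w_0 \sqrt{1 + ((z - \gamma)/d)^2}} with \eqn{w_0 = 1.3} px,
#' depth scale \eqn{d = 400} nm and focal offsets \eqn{\gamma = +200} nm
#' (x) and \eqn{-200} nm (y), sampled noise-free every 25 nm over
#' \eqn{z \in [-400, 400]} nm and fitted by [fit_calibration()].  This is a
#' synthetic stand-in for a measured bead-stack calibration, not a
#' measurement of any particular instrument.
#'
#' @param pixel_size_nm Pixel size recorded in the calibration.
#' @return An `astig_calibration`.
#' @export
default_calibration <- function(pixel_size_nm = 160) {
  key <- paste0("default_", pixel_size_nm)
  if (!is.null(the[[key]])) return(the[[key]])
  z <- seq(-400, 400, by = 25)
  w0 <- 1.3; d <- 400
  data <- tibble(
    z_nm = z,
    wx_px = w0 * sqrt(1 + ((z - 200) / d)^2),
    wy_px = w0 * sqrt(1 + ((z + 200) / d)^2)
  )
  cal <- suppressWarnings(fit_calibration(data, pixel_size_nm = pixel_size_nm))
  cal$meta$synthetic <- TRUE
  the[[key]] <- cal
  cal
}

#' Write / read a calibration file
#'
#' Calibrations are stored as flat JSON with fields `coeff_wx`, `coeff_wy`,
#' `coeff_e` (5 numbers each, lowest order first), `z_min`, `z_max`,
#' `z_zero`, `pixel_size_nm` and `meta`.  Full precision is kept so a
#' write -> read -> write cycle is byte-identical.
#'
#' @param curve An `astig_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns an `astig_calibration`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "astig_calibration"))
  payload <- list(
    format = "gradfit3d-calibration-1",
    coeff_wx = curve$coeff_wx, coeff_wy = curve$coeff_wy,
    coeff_e = curve$coeff_e,
    z_min = curve$z_min, z_max = curve$z_max, z_zero = curve$z_zero,
    pixel_size_nm = curve$pixel_size_nm,
    meta = curve$meta
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::fromJSON(readLines(path))
  if (!identical(p$format, "gradfit3d-calibration-1")) {
    stop_invalid("Not a gradfit3d calibration file.")
  }
  new_calibration(p$coeff_wx, p$coeff_wy, p$coeff_e, p$z_min, p$z_max,
                  p$z_zero, p$pixel_size_nm, meta = as.list(p$meta))
}

#' @export
print.astig_calibration <- function(x, ...) {
  cat(sprintf(
    "<astig_calibration> quartic w_x/w_y/e curves, z in [%.1f, %.1f] nm (zero at raw %.1f nm)\n",
    x$z_min, x$z_max, x$z_zero))
  if (isTRUE(x$meta$synthetic)) cat("  (synthetic default calibration)\n")
  invisible(x)
}

#' @method tidy astig_calibration
#' @export
tidy.astig_calibration <- function(x, ...) {
  tidyr::expand_grid(curve = c("w_x", "w_y", "e"), order = 0:4) |>
    dplyr::mutate(coefficient = c(x$coeff_wx, x$coeff_wy, x$coeff_e))
}

#' @method glance astig_calibration
#' @export
glance.astig_calibration <- function(x, ...) {
  ends <- eval_calibration(x, c(x$z_min, x$z_max))
  tibble(degree = 4L, z_min = x$z_min, z_max = x$z_max, z_zero = x$z_zero,
         e_min = min(ends$e), e_max = max(ends$e),
         pixel_size_nm = x$pixel_size_nm,
         synthetic = isTRUE(x$meta$synthetic))
}

#' Plot a calibration's width and ellipticity curves
#'
#' @param object An `astig_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot astig_calibration
#' @export
autoplot.astig_calibration <- function(object, ...) {
  grid <- eval_calibration(object, seq(object$z_min, object$z_max,
                                       length.out = 200))
  long <- grid |>
    tidyr::pivot_longer(c("w_x", "w_y", "e"), names_to = "curve")
  ggplot2::ggplot(long, ggplot2::aes(.data$z_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "z (nm)", y = NULL,
                  title = "Axial calibration curves")
}
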