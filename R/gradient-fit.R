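## Core algorithm: closed-form, single-iteration estimation of the lateral
## centre (x_c, y_c) and ellipticity e of an astigmatic PSF from the
## gradient-direction field of its ROI.
##
## For an elliptical Gaussian the exact gradient at (m, n) points along
## -(e (m - x_c), (n - y_c)) with e = (w_y/w_x)^2.  The deviation of a
## measured gradient g from that direction is the angle theta between them;
## for small theta, sin(theta) is the normalised cross product
##
##   sin(theta) = [gx (n - y_c) - e gy (m - x_c)] / (|g| |v|),
##   v = (e (m - x_c), (n - y_c)).
##
## The total deviation D = sum W sin(theta)^2 is minimised.  Freezing |v|
## (and the weights) at the centroid pre-estimate makes the residual linear
## in (e, u, y_c) with u = e x_c, so dD/d(e, u, y_c) = 0 is one 3 x 3
## linear solve -- a single iteration by construction.

kernel_var_1d <- function(k) {
  t <- seq_along(k) - (length(k) + 1) / 2
  sum(k * t^2) / sum(k)
}

#' Gradient operator pairs
#'
#' Builds the convolution kernel pair used to measure the gradient field,
#' together with the sub-pixel offset at which the convolved gradient is
#' sampled and the effective isotropic blur variance of the operator
#' (pixel integration plus finite differencing plus any smoothing), in px^2.
#'
#' Available operators:
#' \describe{
#'   \item{`smooth5` (default)}{Central difference combined with a 3-tap
#'     Gaussian (sigma 1) along the derivative axis and a 5-tap Gaussian
#'     along the cross axis whose variance is matched to the derivative
#'     axis.  Variance matching makes the operator blur isotropic, so the
#'     measured direction field is exactly that of the PSF convolved with an
#'     isotropic kernel: centres are unaffected and the ellipticity of the
#'     smoothed field relates to the PSF ellipticity in closed form.
#'     Samples sit at pixel centres.}
#'   \item{`central3`}{Plain central difference with a variance-matched
#'     (1, 4, 1)/6 cross smoother; 3 x 3 support, samples at pixel centres.}
#'   \item{`corner2`}{2 x 2 diagonal-difference (Roberts-style) kernels
#'     sampling at pixel corners (offset +0.5).  Minimal support and minimal
#'     blur, but the noisiest gradient estimate; its small blur anisotropy
#'     (1/6 vs 1/3 px^2) is summarised by the mean.}
#' }
#'
#' @param name One of `"smooth5"`, `"central3"`, `"corner2"`.
#' @return An object of class `gradient_operators`: kernels `kx`, `ky`
#'   (with `ky` the transpose of `kx`), `offset`, `blur_var`, `name`.
#' @export
gradient_operators <- function(name = c("smooth5", "central3", "corner2")) {
  name <- match.arg(name)
  if (name == "corner2") {
    kx <- matrix(c(-1, -1, 1, 1) / 2, 2, 2, byrow = TRUE)
    offset <- 0.5
    blur_var <- 1 / 12 + mean(c(1 / 12, 1 / 4))
  } else if (name == "central3") {
    kx <- outer(c(-0.5, 0, 0.5), c(1, 4, 1) / 6)
    offset <- 1
    blur_var <- 1 / 12 + 1 / 3
  } else {
    gd <- dnorm(-1:1, sd = 1); gd <- gd / sum(gd)
    vd <- kernel_var_1d(gd)
    target <- 1 / 3 + vd
    sig <- uniroot(function(s) {
      k <- dnorm(-2:2, sd = s)
      kernel_var_1d(k / sum(k)) - target
    }, c(0.2, 4))$root
    gs <- dnorm(-2:2, sd = sig); gs <- gs / sum(gs)
    d5 <- convolve(c(-0.5, 0, 0.5), rev(gd), type = "open")
    kx <- outer(d5, gs)
    offset <- 2
    blur_var <- 1 / 12 + target
  }
  structure(
    list(kx = kx, ky = t(kx), offset = offset, blur_var = blur_var,
         name = name),
    class = "gradient_operators"
  )
}

#' @export
print.gradient_operators <- function(x, ...) {
  cat(sprintf("<gradient_operators> '%s', %d x %d kernels, sample offset %.1f px, blur %.3f px^2\n",
              x$name, nrow(x$kx), ncol(x$kx), x$offset, x$blur_var))
  invisible(x)
}

## valid-region convolution of a matrix with a small kernel (no padding);
## separable kernels (rank 1, as all the gradient operators are) use two
## 1D passes
conv_valid <- function(a, k) {
  ka <- nrow(k); kb <- ncol(k)
  nr <- nrow(a) - ka + 1L; nc <- ncol(a) - kb + 1L
  sv <- svd(k, nu = 1, nv = 1)
  if (ka > 1 && kb > 1 && sv$d[2] < 1e-12 * sv$d[1]) {
    kr <- sv$u[, 1] * sv$d[1]
    kc <- sv$v[, 1]
    tmp <- matrix(0, nr, ncol(a))
    for (i in seq_len(ka)) tmp <- tmp + kr[i] * a[i:(i + nr - 1L), ]
    out <- matrix(0, nr, nc)
    for (j in seq_len(kb)) out <- out + kc[j] * tmp[, j:(j + nc - 1L)]
    return(out)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * a[i:(i + nr - 1L), j:(j + nc - 1L)]
    }
  }
  out
}

#' Measure the gradient field of an ROI
#'
#' Valid-region convolution of the raw ROI with both gradient kernels; no
#' padding, so no invented samples.  Sample coordinates are recorded in the
#' ROI frame at the operator's sub-pixel offset.  Weights are initialised to
#' the gradient-quality weight (squared gradient magnitude over local mean
#' intensity) but are not yet position-dependent; [apply_weights()] applies
#' the central-area mask.
#'
#' @param roi A [spot_roi()].
#' @param operators A [gradient_operators()] pair.
#' @return A `gradient_field` tibble with columns `m`, `n`, `gx`, `gy`,
#'   `intensity`, `weight`.
#' @export
compute_gradient_field <- function(roi, operators = gradient_operators()) {
  stopifnot(inherits(roi, "spot_roi"))
  a <- roi$pixels
  if (nrow(a) < nrow(operators$kx) || ncol(a) < ncol(operators$kx)) {
    stop_invalid("ROI is smaller than the gradient kernels.")
  }
  gx <- conv_valid(a, operators$kx)
  gy <- conv_valid(a, operators$ky)
  footprint <- matrix(1, nrow(operators$kx), ncol(operators$kx)) /
    length(operators$kx)
  intensity <- conv_valid(a, footprint)
  pos <- (seq_len(nrow(gx)) - 1) + operators$offset
  m <- matrix(pos, nrow(gx), ncol(gx))
  n <- t(matrix((seq_len(ncol(gx)) - 1) + operators$offset,
                ncol(gx), nrow(gx)))
  g2 <- gx^2 + gy^2
  field <- tibble::new_tibble(
    list(m = as.vector(m), n = as.vector(n),
         gx = as.vector(gx), gy = as.vector(gy),
         intensity = as.vector(intensity),
         weight = as.vector(g2 / pmax(intensity, 1e-12))),
    nrow = length(gx))
  structure(field, operators = operators,
            class = c("gradient_field", class(field)))
}

#' Centroid pre-estimate of centre and ellipticity
#'
#' Background is estimated as the mean of the ROI's border ring and
#' subtracted.  The centre is the intensity-weighted centre of mass of the
#' positive part of the residual.  Second central moments additionally
#' subtract the clipped-noise pedestal, estimated from the border ring
#' itself (on noise-free input the pedestal estimate is zero), giving
#' nearly unbiased per-axis variances; the initial ellipticity is their
#' ratio with the pixel-integration variance 1/12 removed, matching the
#' shared squared-ratio convention.
#'
#' @param roi A [spot_roi()].
#' @return An `init_estimate` list: `x0`, `y0`, `e0`, `var_x`, `var_y`,
#'   `background`, `pedestal`, `photons`.
#' @export
centroid_init <- function(roi) {
  stopifnot(inherits(roi, "spot_roi"))
  a <- roi$pixels
  s <- nrow(a)
  ix <- 0:(s - 1)
  border <- c(a[1, ], a[s, ], a[2:(s - 1), 1], a[2:(s - 1), s])
  bg <- mean(border)
  bc <- pmax(a - bg, 0)
  total <- sum(bc)
  if (total <= 0) {
    stop_degenerate("ROI has no signal above the background floor.")
  }
  x0 <- sum(rowSums(bc) * ix) / total
  y0 <- sum(colSums(bc) * ix) / total
  pedestal <- mean(pmax(border - bg, 0))
  wm <- bc - pedestal
  tm <- sum(wm)
  if (tm <= 0) {
    stop_degenerate("ROI has no signal above the noise pedestal.")
  }
  var_x <- sum(rowSums(wm) * (ix - x0)^2) / tm
  var_y <- sum(colSums(wm) * (ix - y0)^2) / tm
  w2x <- max(var_x - 1 / 12, 0.05)
  w2y <- max(var_y - 1 / 12, 0.05)
  structure(
    list(x0 = x0, y0 = y0, e0 = w2y / w2x,
         var_x = var_x, var_y = var_y,
         background = bg, pedestal = pedestal, photons = total),
    class = "init_estimate"
  )
}

## ellipticity of the operator-blurred gradient field implied by the
## centroid moments; used for the frozen direction normalisation
init_field_ellipticity <- function(init, blur_var) {
  w2x <- max(init$var_x - 1 / 12, 0.05)
  w2y <- max(init$var_y - 1 / 12, 0.05)
  (w2y + blur_var) / (w2x + blur_var)
}

#' Apply the central-area mask to a gradient field
#'
#' Samples farther than `mask_radius` from the centroid pre-estimate get
#' weight 0: outer samples carry little signal and are easily corrupted by
#' background and neighbouring emitters.  Samples with zero gradient
#' magnitude (undefined direction) are also zeroed.  Among samples at equal
#' distance from the centre, a larger gradient magnitude never yields a
#' smaller weight.
#'
#' @param field A `gradient_field` from [compute_gradient_field()].
#' @param init An `init_estimate` from [centroid_init()].
#' @param mask_radius Central-area radius in px (default 4).
#' @return The field with masked weights.
#' @export
apply_weights <- function(field, init, mask_radius = 4) {
  stopifnot(inherits(field, "gradient_field"), inherits(init, "init_estimate"))
  d2 <- (field$m - init$x0)^2 + (field$n - init$y0)^2
  g2 <- field$gx^2 + field$gy^2
  field$weight <- ifelse(d2 > mask_radius^2 | g2 <= 0, 0, field$weight)
  field
}

## effective per-sample weight of the squared residual:
## Omega = W / (|g|^2 (|v0|^2 + rho_floor)), with W = |g|^2 / intensity
residual_weights <- function(field, init, e0_field, rho_floor) {
  rho2 <- e0_field^2 * (field$m - init$x0)^2 + (field$n - init$y0)^2 +
    rho_floor
  g2 <- field$gx^2 + field$gy^2
  ifelse(field$weight > 0, field$weight / (pmax(g2, 1e-300) * rho2), 0)
}

#' Weighted gradient-direction deviation objective
#'
#' Evaluates the total deviation `D(x_c, y_c, e)` that
#' [solve_gradient_fit()] minimises, with the direction normalisation and
#' weights frozen at the centroid pre-estimate.  Exposed so the closed-form
#' solution can be checked against generic numerical minimisers of the
#' identical objective.
#'
#' @param field A weighted `gradient_field` (after [apply_weights()]).
#' @param init The `init_estimate` the objective was linearised at.
#' @param x_c,y_c,e Parameters at which to evaluate `D`.
#' @param rho_floor Regularisation (px^2) added to the squared direction
#'   norm; tames the undefined gradient direction within ~1 px of the
#'   centre (default 1).
#' @return The scalar deviation `D`.
#' @export
gradfit_objective <- function(field, init, x_c, y_c, e, rho_floor = 1) {
  ops <- attr(field, "operators")
  e0f <- init_field_ellipticity(init, ops$blur_var)
  om <- residual_weights(field, init, e0f, rho_floor)
  r <- field$gx * (field$n - y_c) - e * field$gy * (field$m - x_c)
  sum(om * r^2)
}

#' Closed-form single-iteration gradient fit
#'
#' Minimises the weighted squared angular deviation between the measured
#' gradient field and the elliptical direction field implied by
#' `(x_c, y_c, e)`.  With the direction normalisation frozen at the
#' centroid pre-estimate the objective is exactly quadratic in
#' `(e, u, y_c)` with `u = e x_c`, so the minimiser is obtained from a
#' single 3 x 3 linear solve -- no iteration, no convergence loop.
#'
#' The fitted ellipticity `e` refers to the operator-smoothed gradient
#' field.  The result also carries `e_psf`, the PSF-frame ellipticity
#' obtained by removing the operator's known isotropic blur variance using
#' the moment-based width estimate (see the package vignette for the
#' bias/variance trade-off between the two).
#'
#' @param field A weighted `gradient_field` (after [apply_weights()]).
#' @param init An `init_estimate` from [centroid_init()].
#' @param rho_floor See [gradfit_objective()].
#' @param max_condition Condition-number bound above which the normal
#'   system is declared degenerate (default 1e12).
#' @return A `gradfit_result`: `x_c`, `y_c`, `e`, `e_psf`, `deviation`
#'   (D at the solution), `deviation_init`, `n_gradients_used`, `flags`,
#'   `n_linear_solves` (always 1), and the `init` used.
#' @export
solve_gradient_fit <- function(field, init, rho_floor = 1,
                               max_condition = 1e12) {
  stopifnot(inherits(field, "gradient_field"), inherits(init, "init_estimate"))
  ops <- attr(field, "operators")
  used <- field$weight > 0
  if (sum(used) < 3) {
    stop_degenerate("Fewer than 3 weighted gradient samples; cannot fit 3 unknowns.")
  }
  e0f <- init_field_ellipticity(init, ops$blur_var)
  om <- residual_weights(field, init, e0f, rho_floor)
  ## residual r = b + a . p with p = (e, u, y_c), u = e x_c
  a1 <- -field$gy * field$m
  a2 <- field$gy
  a3 <- -field$gx
  b <- field$gx * field$n
  m <- matrix(c(
    sum(om * a1 * a1), sum(om * a1 * a2), sum(om * a1 * a3),
    sum(om * a1 * a2), sum(om * a2 * a2), sum(om * a2 * a3),
    sum(om * a1 * a3), sum(om * a2 * a3), sum(om * a3 * a3)), 3, 3)
  v <- -c(sum(om * a1 * b), sum(om * a2 * b), sum(om * a3 * b))
  cond <- tryCatch(kappa(m, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > max_condition) {
    stop_degenerate(
      sprintf("Normal system is singular or ill-conditioned (condition %.3g).", cond),
      condition_number = cond)
  }
  p <- solve(m, v)
  e_field <- p[1]
  flags <- character(0)
  if (e_field <= 0) {
    stop_degenerate("Fit produced a non-positive ellipticity.")
  }
  x_c <- p[2] / e_field
  y_c <- p[3]
  w2x <- max(init$var_x - 1 / 12, 0.05)
  e_psf <- max((e_field * (w2x + ops$blur_var) - ops$blur_var) / w2x, 1e-3)
  d_sol <- sum(om * (b + a1 * e_field + a2 * p[2] + a3 * y_c)^2)
  ## D at the linearisation point, from the same weighted system
  d_init <- sum(om * (b + a1 * e0f + a2 * e0f * init$x0 + a3 * init$y0)^2)
  structure(
    list(x_c = x_c, y_c = y_c, e = e_field, e_psf = e_psf,
         deviation = d_sol, deviation_init = d_init,
         n_gradients_used = sum(used), flags = flags,
         n_linear_solves = 1L, condition_number = cond, init = init,
         operators = ops$name),
    class = "gradfit_result"
  )
}

#' @export
print.gradfit_result <- function(x, ...) {
  cat(sprintf(
    "<gradfit_result> centre (%.4f, %.4f) px, e = %.4f (PSF frame %.4f), D = %.4g, %d gradients\n",
    x$x_c, x$y_c, x$e, x$e_psf, x$deviation, x$n_gradients_used))
  invisible(x)
}

#' @method tidy gradfit_result
#' @export
tidy.gradfit_result <- function(x, ...) {
  tibble(term = c("x_c", "y_c", "e"),
         estimate = c(x$x_c, x$y_c, x$e))
}

#' @method glance gradfit_result
#' @export
glance.gradfit_result <- function(x, ...) {
  tibble(deviation = x$deviation, deviation_init = x$deviation_init,
         n_gradients_used = x$n_gradients_used,
         n_linear_solves = x$n_linear_solves,
         condition_number = x$condition_number,
         operators = x$operators)
}

#' Localization configuration
#'
#' @param operator Gradient operator name (see [gradient_operators()]).
#' @param mask_radius Central-area mask radius in px.
#' @param rho_floor Direction-norm regularisation in px^2.
#' @param deblur_ellipticity If `TRUE`, decode z from the blur-corrected
#'   PSF-frame ellipticity instead of the operator-field ellipticity; see
#'   the vignette for when this is appropriate.
#' @param roi_size ROI side length in px.
#' @return A `gradfit_config` list.
#' @export
gradfit_config <- function(operator = "smooth5", mask_radius = 4,
                           rho_floor = 1, deblur_ellipticity = FALSE,
                           roi_size = 15L) {
  structure(
    list(operator = operator, mask_radius = mask_radius,
         rho_floor = rho_floor, deblur_ellipticity = deblur_ellipticity,
         roi_size = as.integer(roi_size)),
    class = "gradfit_config"
  )
}

#' Localize one ROI in 3D
#'
#' Chains [compute_gradient_field()], [centroid_init()], [apply_weights()],
#' [solve_gradient_fit()] and [z_from_ellipticity()], converting the fitted
#' ROI-frame centre to frame-global nanometres.  Photons are estimated as
#' the background-subtracted ROI sum.
#'
#' @param roi A [spot_roi()].
#' @param operators A [gradient_operators()] pair.
#' @param curve An `astig_calibration` for z decoding, or `NULL` for 2D.
#' @param config A [gradfit_config()].
#' @param pixel_size_nm Pixel size in nm.
#' @return One-row tibble with the localization-table schema:
#'   `frame`, `x_nm`, `y_nm`, `z_nm`, `ellipticity`, `photons`,
#'   `background`, `flags`.
#' @export
localize_roi <- function(roi, operators = gradient_operators(),
                         curve = NULL, config = gradfit_config(),
                         pixel_size_nm = 160) {
  field <- compute_gradient_field(roi, operators)
  init <- centroid_init(roi)
  ## no-emitter guard: require a peak clearly above the background noise
  peak <- max(roi$pixels) - init$background
  if (peak < 5 * sqrt(max(init$background, 1))) {
    stop_degenerate("ROI peak is indistinguishable from background noise.")
  }
  field <- apply_weights(field, init, mask_radius = config$mask_radius)
  fit <- solve_gradient_fit(field, init, rho_floor = config$rho_floor)
  e_out <- if (isTRUE(config$deblur_ellipticity)) fit$e_psf else fit$e
  flags <- fit$flags
  z <- NA_real_
  if (!is.null(curve)) {
    zd <- if (isTRUE(config$deblur_ellipticity)) {
      ## de-blurred PSF-frame ellipticity inverts the plain z-e curve
      z_from_ellipticity(curve, e_out)
    } else {
      ## field ellipticity inverts the operator-consistent blurred curve
      z_from_field_ellipticity(curve, e_out, operators$blur_var)
    }
    z <- zd$z_nm
    if (zd$range_clipped) flags <- c(flags, "range_clipped")
  }
  tibble::new_tibble(list(
    frame = roi$frame_index,
    x_nm = (roi$origin[1] + fit$x_c) * pixel_size_nm,
    y_nm = (roi$origin[2] + fit$y_c) * pixel_size_nm,
    z_nm = z,
    ellipticity = e_out,
    photons = init$photons,
    background = init$background,
    flags = paste(flags, collapse = ";")
  ), nrow = 1L)
}

#' Localize every frame of a stack
#'
#' Runs detection (smoothing, local-maximum candidate search, ROI
#' extraction) and the gradient fit on each frame of a stack.  ROIs whose
#' fit degenerates are dropped; their count is reported in the
#' `n_failed` attribute.
#'
#' @param stack A `frame_stack` (from [simulate_stack()] or [read_stack()]).
#' @param curve An `astig_calibration`, or `NULL` for 2D localization.
#' @param config A [gradfit_config()].
#' @param threshold,k,detect_sigma Candidate-detection settings passed to
#'   [find_candidates()] / [denoise_frame()].
#' @return A localization tibble (one row per accepted localization).
#' @export
localize_stack <- function(stack, curve = NULL, config = gradfit_config(),
                           threshold = NULL, k = 4, detect_sigma = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  ops <- gradient_operators(config$operator)
  px <- stack$camera$pixel_size_nm
  n_failed <- 0L
  rows <- list()
  for (fi in seq_along(stack$frames)) {
    frame <- stack$frames[[fi]]
    cands <- find_candidates(denoise_frame(frame, sigma = detect_sigma),
                             threshold = threshold, k = k,
                             suppression_radius = config$roi_size / 2)
    rois <- extract_rois(frame, cands, size = config$roi_size,
                         frame_index = fi)
    for (roi in rois) {
      loc <- tryCatch(
        localize_roi(roi, ops, curve, config, pixel_size_nm = px),
        gradfit3d_degenerate = function(e) NULL)
      if (is.null(loc)) n_failed <- n_failed + 1L else {
        rows[[length(rows) + 1L]] <- loc
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_localizations()
  attr(out, "n_failed") <- n_failed
  out
}
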