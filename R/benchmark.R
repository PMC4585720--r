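## Benchmark harness: Monte-Carlo precision/accuracy vs depth, Cramer-Rao
## lower bound, MSD for tracking, and a timing harness.

#' Simulation protocol for a precision study
#'
#' Defaults follow the standard numerical evaluation for astigmatic
#' localizers: 33 x 33 px frames at 160 nm pixels, one emitter per frame
#' uniformly placed in the central pixel, 5000 signal photons, 100
#' background photons per pixel, Poisson noise, 1000 frames at each of 9
#' axial positions from -400 to +400 nm, 15 x 15 px ROIs.
#'
#' @param z_grid Axial positions in nm.
#' @param photons Signal photons per emitter.
#' @param background Background photons per pixel.
#' @param frames_per_z Frames simulated at each z.
#' @param camera A [camera_model()]; its background is overridden by
#'   `background`.
#' @param calibration An `astig_calibration` used both to derive the
#'   simulated widths and to decode z.
#' @param roi_size ROI side length in px.
#' @return A `precision_protocol` list.
#' @export
precision_protocol <- function(z_grid = seq(-400, 400, by = 100),
                               photons = 5000, background = 100,
                               frames_per_z = 1000,
                               camera = camera_model(),
                               calibration = default_calibration(),
                               roi_size = 15L) {
  camera$background <- background
  structure(
    list(z_grid = z_grid, photons = photons, background = background,
         frames_per_z = frames_per_z, camera = camera,
         calibration = calibration, roi_size = as.integer(roi_size)),
    class = "precision_protocol"
  )
}

## extract the truth-centred ROI of a simulated single-emitter frame
central_roi <- function(frame, roi_size, frame_index) {
  half <- roi_size %/% 2
  ci <- (nrow(frame) - 1L) %/% 2L
  cj <- (ncol(frame) - 1L) %/% 2L
  spot_roi(frame[(ci - half):(ci + half) + 1L, (cj - half):(cj + half) + 1L],
           origin = c(ci - half, cj - half), frame_index = frame_index)
}

fit_one_roi <- function(roi, algorithm, curve, config, pixel_size_nm) {
  switch(
    algorithm,
    gradient = localize_roi(roi, gradient_operators(config$operator),
                            curve, config, pixel_size_nm),
    centroid_wd = localize_centroid_wd(roi, curve, pixel_size_nm),
    nlls_wd = ,
    nlls_wa = {
      fit <- fit_psf_nlls(roi)
      if (!fit$converged) stop_degenerate("NLLS did not converge.")
      zd <- if (algorithm == "nlls_wd") {
        z_from_widths_wd(curve, fit$w_x, fit$w_y)
      } else {
        z_from_widths_wa(curve, fit$w_x, fit$w_y)
      }
      tibble(frame = roi$frame_index,
             x_nm = (roi$origin[1] + fit$x_c) * pixel_size_nm,
             y_nm = (roi$origin[2] + fit$y_c) * pixel_size_nm,
             z_nm = zd$z_nm,
             ellipticity = ellipticity_from_widths(fit$w_x, fit$w_y),
             photons = fit$photons, background = fit$background,
             flags = if (zd$range_clipped) "range_clipped" else "")
    },
    mle_wa = {
      fit <- fit_psf_mle(roi)
      if (!fit$converged) stop_degenerate("MLE did not converge.")
      zd <- z_from_widths_wa(curve, fit$w_x, fit$w_y)
      tibble(frame = roi$frame_index,
             x_nm = (roi$origin[1] + fit$x_c) * pixel_size_nm,
             y_nm = (roi$origin[2] + fit$y_c) * pixel_size_nm,
             z_nm = zd$z_nm,
             ellipticity = ellipticity_from_widths(fit$w_x, fit$w_y),
             photons = fit$photons, background = fit$background,
             flags = if (zd$range_clipped) "range_clipped" else "")
    },
    stop_invalid(paste("Unknown algorithm:", algorithm))
  )
}

#' Monte-Carlo localization precision and accuracy study
#'
#' Simulates the protocol's frames at every axial position, localizes each
#' frame's truth-centred ROI with every requested algorithm, and aggregates
#' per-axis precision (standard deviation of the estimates) and accuracy
#' (root-mean-square error against the recorded truth).  All algorithms see
#' the same simulated frames; the whole study is deterministic given
#' `seed`.  Fits whose decoded z was range-clipped are included (their
#' count is reported); fits that fail outright are excluded and counted.
#'
#' @param protocol A [precision_protocol()].
#' @param algorithms Subset of `c("gradient", "centroid_wd", "nlls_wd",
#'   "nlls_wa", "mle_wa")`.
#' @param seed Integer seed; per-z stream seeds are derived from it.
#' @param config A [gradfit_config()] for the gradient algorithm.
#' @return A `precision_report` tibble: one row per (algorithm, z) with
#'   columns `std_x`, `std_y`, `std_z`, `rmse_x`, `rmse_y`, `rmse_z` (nm),
#'   `n_fits`, `n_failed`, `n_clipped`.
#' @export
run_precision_study <- function(protocol = precision_protocol(),
                                algorithms = "gradient",
                                seed = 1L,
                                config = gradfit_config()) {
  stopifnot(inherits(protocol, "precision_protocol"))
  px <- protocol$camera$pixel_size_nm
  rows <- list()
  for (zi in seq_along(protocol$z_grid)) {
    z <- protocol$z_grid[zi]
    stack <- simulate_stack(
      protocol$frames_per_z, protocol$camera, protocol$calibration,
      z_nm = z, photons = protocol$photons,
      seed = as.integer(seed) + 1000L * zi)
    rois <- lapply(seq_along(stack$frames), function(i) {
      central_roi(stack$frames[[i]], protocol$roi_size, i)
    })
    for (alg in algorithms) {
      fits <- lapply(rois, function(roi) {
        tryCatch(
          fit_one_roi(roi, alg, protocol$calibration, config, px),
          gradfit3d_degenerate = function(e) NULL)
      })
      ok <- !vapply(fits, is.null, logical(1))
      est <- dplyr::bind_rows(fits[ok])
      truth <- stack$truth[ok, ]
      dx <- est$x_nm - truth$x_px * px
      dy <- est$y_nm - truth$y_px * px
      dz <- est$z_nm - truth$z_nm
      rows[[length(rows) + 1L]] <- tibble(
        algorithm = alg, z_nm = z,
        ## precision: spread of the localization error, i.e. the std of the
        ## estimated positions after removing the per-frame true position
        std_x = sd(dx), std_y = sd(dy), std_z = sd(dz),
        rmse_x = sqrt(mean(dx^2)), rmse_y = sqrt(mean(dy^2)),
        rmse_z = sqrt(mean(dz^2)),
        bias_x = mean(dx), bias_y = mean(dy), bias_z = mean(dz),
        n_fits = sum(ok), n_failed = sum(!ok),
        n_clipped = sum(grepl("range_clipped", est$flags))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, protocol = protocol, seed = seed,
            class = c("precision_report", class(out)))
}

#' Plot a precision report
#'
#' @param object A `precision_report`.
#' @param metric `"std"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object: per-axis precision vs depth, one line per
#'   algorithm.
#' @method autoplot precision_report
#' @export
autoplot.precision_report <- function(object, metric = c("std", "rmse"), ...) {
  metric <- match.arg(metric)
  cols <- paste0(metric, "_", c("x", "y", "z"))
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "axis") |>
    dplyr::mutate(axis = sub(paste0(metric, "_"), "", .data$axis))
  ggplot2::ggplot(long, ggplot2::aes(.data$z_nm, .data$value,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "z (nm)", y = paste(metric, "(nm)"),
                  title = "Localization precision vs depth")
}

#' Cramer-Rao lower bound for the 6-parameter integrated-Gaussian model
#'
#' Assembles the Fisher information of the Poisson noise model,
#' \eqn{I_{ab} = \sum_k (\partial\mu_k/\partial a)(\partial\mu_k/\partial b)/\mu_k},
#' over an ROI-sized grid using the analytic model derivatives, and returns
#' the square roots of the diagonal of its inverse.
#'
#' @param truth An [emitter_truth()] (centre in ROI coordinates).
#' @param camera A [camera_model()] providing the background; the grid is
#'   `roi_size` squared.
#' @param roi_size Grid side in px (default 15).
#' @return Named vector of lower-bound standard deviations for
#'   `x`, `y` (px), `wx`, `wy` (px), `N`, `b` (photons).
#' @export
crlb <- function(truth, camera = camera_model(), roi_size = 15L) {
  stopifnot(inherits(truth, "emitter_truth"))
  p <- c(truth$x_c, truth$y_c, truth$w_x, truth$w_y, truth$photons,
         camera$background)
  mu <- as.vector(psf_model_mu(p, roi_size, roi_size))
  if (any(mu <= 0)) stop_invalid("Model mean must be positive everywhere.")
  jac <- psf_model_jac(p, roi_size, roi_size)
  fi <- crossprod(jac, jac / mu)
  zero_info <- diag(fi) <= .Machine$double.eps
  if (any(zero_info)) {
    stop_invalid(paste("Fisher information is singular; non-identifiable:",
                       paste(colnames(jac)[zero_info], collapse = ", ")))
  }
  inv <- tryCatch(solve(fi), error = function(e) {
    stop_invalid("Fisher information is numerically singular.")
  })
  setNames(sqrt(diag(inv)), c("x", "y", "wx", "wy", "N", "b"))
}

#' Mean square displacement of a trajectory
#'
#' \eqn{MSD(\tau) = } mean over all overlapping windows of the squared
#' displacement between samples separated by lag \eqn{\tau}.  Requires a
#' uniform sampling interval.
#'
#' @param traj Data frame with column `t` (seconds) and coordinate columns
#'   (`x`, `y`, `z` as available, nm).
#' @param max_lag Largest lag, in steps.
#' @param axes Coordinate columns to use (defaults to those present).
#' @return Tibble with columns `lag_s`, `msd_nm2`, `n_pairs`.
#' @export
msd <- function(traj, max_lag = NULL, axes = intersect(c("x", "y", "z"),
                                                       names(traj))) {
  if (nrow(traj) < 2) stop_invalid("Trajectory needs at least 2 samples.")
  tt <- traj$t
  if (any(diff(tt) <= 0)) stop_invalid("Time must be strictly increasing.")
  dt <- diff(tt)
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    stop_invalid("Trajectory sampling interval is not uniform.")
  }
  r <- as.matrix(traj[, axes, drop = FALSE])
  n <- nrow(r)
  max_lag <- max_lag %||% (n - 1L)
  max_lag <- min(max_lag, n - 1L)
  purrr::map_dfr(seq_len(max_lag), function(k) {
    d2 <- rowSums((r[(1 + k):n, , drop = FALSE] -
                     r[1:(n - k), , drop = FALSE])^2)
    tibble(lag_s = k * dt[1], msd_nm2 = mean(d2), n_pairs = length(d2))
  })
}

#' Wall-clock timing harness
#'
#' Mean wall-clock seconds per localization for a fitting function over a
#' set of ROIs, after one warm-up pass.  Timings are informational only --
#' they depend on the machine -- so the result carries a hardware
#' descriptor and is never asserted against published numbers.
#'
#' @param fit_fun Function taking one [spot_roi()].
#' @param rois List of ROIs (1000 or more recommended).
#' @param warmup Number of warm-up fits (default `min(10, length(rois))`).
#' @return Mean seconds per localization, with attributes `n`, `total_s`
#'   and `hardware`.
#' @export
time_localizations <- function(fit_fun, rois, warmup = NULL) {
  warmup <- warmup %||% min(10L, length(rois))
  for (roi in rois[seq_len(warmup)]) {
    try(fit_fun(roi), silent = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  for (roi in rois) try(fit_fun(roi), silent = TRUE)
  total <- proc.time()[["elapsed"]] - t0
  structure(total / length(rois), n = length(rois), total_s = total,
            hardware = paste(Sys.info()[["sysname"]], Sys.info()[["machine"]],
                             R.version.string))
}
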