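test_that("gradient kernels have zero sum and the transpose relation", {
  for (nm in c("smooth5", "central3", "corner2")) {
    op <- gradient_operators(nm)
    expect_lt(abs(sum(op$kx)), 1e-12)
    expect_lt(abs(sum(op$ky)), 1e-12)
    expect_equal(op$ky, t(op$kx))
  }
})

test_that("gradient field is exact on constant and planar images", {
  for (nm in c("smooth5", "central3", "corner2")) {
    op <- gradient_operators(nm)
    const <- spot_roi(matrix(37.5, 15, 15))
    f <- compute_gradient_field(const, op)
    expect_true(all(abs(f$gx) < 1e-10) && all(abs(f$gy) < 1e-10))
    ## planar ramp a*m + b*n: every sample proportional to (a, b) with one
    ## common positive factor
    a <- 2.5; b <- -1.25
    m <- matrix(0:14, 15, 15); n <- t(m)
    ramp <- spot_roi(a * m + b * n + 100)
    f <- compute_gradient_field(ramp, op)
    expect_equal(f$gx / a, f$gy / b, tolerance = 1e-10)
    expect_true(all(f$gx / a > 0))
  }
  expect_error(
    compute_gradient_field(spot_roi(matrix(1, 3, 3)),
                           gradient_operators("smooth5")),
    class = "gradfit3d_invalid")
})

test_that("measured gradient directions track the analytic field", {
  ## noise-free PSF; for interior samples with above-median magnitude the
  ## angle to the analytic gradient stays below 2 degrees
  tr <- emitter_truth(7.2, 6.9, 1.5, sqrt(1.2) * 1.5, 5000)
  roi <- make_roi(7.2, 6.9, 1.5, sqrt(1.2) * 1.5, background = 0)
  f <- compute_gradient_field(roi, gradient_operators("central3"))
  g_true <- psf_gradient(tr, cbind(f$m, f$n))
  mag <- sqrt(f$gx^2 + f$gy^2)
  keep <- mag > median(mag)
  cosang <- (f$gx * g_true[, 1] + f$gy * g_true[, 2]) /
    (mag * sqrt(rowSums(g_true^2)))
  expect_true(all(acos(pmin(cosang[keep], 1)) < 2 * pi / 180))
})

test_that("weights follow the dual-path transcription and the mask contract", {
  roi <- make_roi(7.3, 6.7, 1.5, 1.3, background = 10)
  op <- gradient_operators("smooth5")
  f <- compute_gradient_field(roi, op)
  ## independent direct per-sample transcription of W = |g|^2 / mean(I)
  k <- nrow(op$kx)
  a <- roi$pixels
  for (idx in c(1L, 17L, 60L, nrow(f))) {
    i <- f$m[idx] - op$offset + 1
    j <- f$n[idx] - op$offset + 1
    patch <- a[i:(i + k - 1), j:(j + k - 1)]
    gx <- sum(patch * op$kx); gy <- sum(patch * op$ky)
    expect_equal(f$weight[idx], (gx^2 + gy^2) / mean(patch),
                 tolerance = 1e-12)
  }
  init <- centroid_init(roi)
  fw <- apply_weights(f, init, mask_radius = 4)
  d2 <- (fw$m - init$x0)^2 + (fw$n - init$y0)^2
  expect_true(all(fw$weight[d2 > 16] == 0))
  expect_true(any(fw$weight[d2 <= 16] > 0))
  ## zero-magnitude samples carry no weight
  flat <- apply_weights(
    compute_gradient_field(spot_roi(matrix(5, 15, 15)), op),
    init, mask_radius = 100)
  expect_lt(max(flat$weight), 1e-20)
})

test_that("centroid matches hand-computed moments and is shift-equivariant", {
  ## toy patch: after floor subtraction two lit pixels remain
  toy <- matrix(0, 5, 5)
  toy[3, 3] <- 2; toy[3, 4] <- 2
  init <- centroid_init(spot_roi(toy))
  expect_equal(init$x0, 2)            # rows 2 (0-based) for both
  expect_equal(init$y0, 2.5)          # mean of columns 2 and 3
  ## symmetric noise-free PSF at the ROI centre
  sym <- centroid_init(make_roi(7, 7, 1.4, 1.4, background = 0))
  expect_equal(sym$x0, 7, tolerance = 1e-9)
  expect_equal(sym$y0, 7, tolerance = 1e-9)
  expect_equal(sym$e0, 1, tolerance = 1e-6)
  ## moving the emitter by an integer vector moves the centroid exactly
  ## (PSF tails at the ROI edge are negligible at these widths)
  i1 <- centroid_init(make_roi(5.3, 5.8, 1.4, 1.2, background = 5))
  i2 <- centroid_init(make_roi(7.3, 6.8, 1.4, 1.2, background = 5))
  expect_equal(i2$x0 - i1$x0, 2, tolerance = 1e-4)
  expect_equal(i2$y0 - i1$y0, 1, tolerance = 1e-4)
  expect_error(centroid_init(spot_roi(matrix(3, 9, 9))),
               class = "gradfit3d_degenerate")
})

solve_roi <- function(roi, op = gradient_operators()) {
  field <- compute_gradient_field(roi, op)
  init <- centroid_init(roi)
  field <- apply_weights(field, init, mask_radius = 4)
  list(fit = solve_gradient_fit(field, init), field = field, init = init)
}

test_that("closed-form solution matches the symmetric fixed point", {
  s <- solve_roi(make_roi(7, 7, 1.4, 1.4, background = 0))
  expect_equal(s$fit$x_c, 7, tolerance = 1e-6)
  expect_equal(s$fit$y_c, 7, tolerance = 1e-6)
  ## e = 1 up to the discrete-kernel asymmetry of the smoothing taps
  expect_equal(s$fit$e, 1, tolerance = 1e-3)
  expect_identical(s$fit$n_linear_solves, 1L)
})

test_that("closed form equals a brute-force minimiser of the same objective", {
  ## spot check here (the acceptance suite runs the 100-case version)
  cases <- expand.grid(dx = c(-0.3, 0.3), dy = c(-0.2, 0.2),
                       e = c(0.8, 1.44))
  for (i in seq_len(nrow(cases))) {
    w_x <- 1.4
    w_y <- sqrt(cases$e[i]) * w_x
    roi <- make_roi(7 + cases$dx[i], 7 + cases$dy[i], w_x, w_y,
                    background = 10)
    s <- solve_roi(roi)
    obj <- function(p) gradfit_objective(s$field, s$init, p[1], p[2], p[3])
    ref <- optim(c(s$init$x0, s$init$y0, s$init$e0), obj,
                 control = list(reltol = 1e-15, maxit = 20000))
    expect_lt(abs(s$fit$x_c - ref$par[1]), 1e-3)
    expect_lt(abs(s$fit$y_c - ref$par[2]), 1e-3)
    expect_lt(abs(s$fit$e - ref$par[3]), 1e-3)
    ## objective never increases relative to the initial point
    d_init <- gradfit_objective(s$field, s$init, s$init$x0, s$init$y0,
                                s$init$e0)
    expect_lte(s$fit$deviation, d_init + 1e-12)
  }
})

test_that("noise-free fits are translation-equivariant and transpose-symmetric", {
  s1 <- solve_roi(make_roi(5.3, 5.8, 1.5, 1.3, background = 10))
  s2 <- solve_roi(make_roi(7.3, 6.8, 1.5, 1.3, background = 10))
  expect_equal(s2$fit$x_c - s1$fit$x_c, 2, tolerance = 1e-4)
  expect_equal(s2$fit$y_c - s1$fit$y_c, 1, tolerance = 1e-4)

  ## transposing the ROI swaps the axes and inverts the ellipticity (up to
  ## the discrete-kernel asymmetry documented in the vignette)
  roi <- make_roi(7.3, 6.8, 1.5, 1.2, background = 10)
  st <- solve_roi(spot_roi(t(roi$pixels)))
  s0 <- solve_roi(roi)
  expect_equal(st$fit$x_c, s0$fit$y_c, tolerance = 1e-3)
  expect_equal(st$fit$y_c, s0$fit$x_c, tolerance = 1e-3)
  expect_equal(st$fit$e, 1 / s0$fit$e, tolerance = 5e-3)
})

test_that("degenerate inputs raise degenerate-fit errors", {
  op <- gradient_operators()
  roi <- make_roi(7, 7, 1.4, 1.4, background = 0)
  field <- compute_gradient_field(roi, op)
  init <- centroid_init(roi)
  ## masking away (almost) everything leaves fewer than 3 usable samples
  starved <- field
  starved$weight[-(1:2)] <- 0
  expect_error(solve_gradient_fit(starved, init),
               class = "gradfit3d_degenerate")
  ## all-parallel gradients give a singular normal system
  m <- matrix(0:14, 15, 15)
  ramp <- spot_roi(3 * m + 50)
  rf <- apply_weights(compute_gradient_field(ramp, op),
                      structure(list(x0 = 7, y0 = 7, e0 = 1,
                                     var_x = 2, var_y = 2, background = 0,
                                     pedestal = 0, photons = 1),
                                class = "init_estimate"),
                      mask_radius = 100)
  expect_error(
    solve_gradient_fit(rf, structure(list(x0 = 7, y0 = 7, e0 = 1,
                                          var_x = 2, var_y = 2,
                                          background = 0, pedestal = 0,
                                          photons = 1),
                                     class = "init_estimate")),
    class = "gradfit3d_degenerate")
})

test_that("localize_roi decodes z consistently and refuses empty ROIs", {
  cal <- default_calibration()
  ## simulated emitter at +200 nm: median decoded z within 15 nm of truth
  st <- simulate_stack(400, camera_model(background = 100), cal,
                       z_nm = 200, photons = 5000, seed = 3L)
  zs <- vapply(seq_along(st$frames), function(i) {
    roi <- spot_roi(st$frames[[i]][10:24, 10:24], origin = c(9, 9),
                    frame_index = i)
    localize_roi(roi, curve = cal)$z_nm
  }, numeric(1))
  expect_lt(abs(median(zs) - 200), 15)

  ## pure background: no localization, degenerate error
  bg <- withr::with_seed(9L, matrix(rpois(225, 100), 15, 15))
  expect_error(localize_roi(spot_roi(bg), curve = cal),
               class = "gradfit3d_degenerate")
})

test_that("precision improves with photon count", {
  sd_at <- function(n_photons) {
    st <- simulate_stack(250, camera_model(background = 100),
                         z_nm = 0, photons = n_photons, seed = 21L)
    est <- vapply(seq_along(st$frames), function(i) {
      roi <- spot_roi(st$frames[[i]][10:24, 10:24], origin = c(9, 9),
                      frame_index = i)
      localize_roi(roi)$x_nm
    }, numeric(1))
    sd(est - st$truth$x_px * 160)
  }
  expect_lt(sd_at(20000), sd_at(5000))
})
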