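test_that("noise-free quartic width curves are recovered exactly", {
  ## generate widths from a known quartic pair whose ellipticity stays
  ## monotone over the sampled range
  cx <- c(1.8, -1.2e-3, 8e-7, 1e-10, 2e-13)
  cy <- c(1.8, +1.2e-3, 8e-7, -1e-10, 2e-13)
  z <- seq(-400, 400, by = 100)
  data <- tibble::tibble(z_nm = z,
                         wx_px = quartic_at(cx, z),
                         wy_px = quartic_at(cy, z))
  cal <- suppressWarnings(fit_calibration(data))
  ## the symmetric pair crosses at z = 0, so no zero shift is applied
  expect_equal(cal$z_zero, 0, tolerance = 0.1)
  expect_equal(cal$coeff_wx, cx, tolerance = 1e-8)
  expect_equal(cal$coeff_wy, cy, tolerance = 1e-8)
  expect_length(cal$coeff_e, 5L)    # stored polynomial degree is 4
})

test_that("replicate measurements reduce to their per-position means", {
  base <- make_width_table(replicates = 1)
  reps <- make_width_table(replicates = 4, noise_sd = 0.03, seed = 5)
  ## symmetric-noise replicates: fitting the replicates equals fitting the
  ## replicate means
  means <- reps |>
    dplyr::group_by(z_nm) |>
    dplyr::summarise(wx_px = mean(wx_px), wy_px = mean(wy_px))
  cal_reps <- suppressWarnings(fit_calibration(reps))
  cal_means <- suppressWarnings(fit_calibration(means))
  expect_equal(cal_reps$coeff_wx, cal_means$coeff_wx, tolerance = 1e-12)
  expect_equal(cal_reps$coeff_e, cal_means$coeff_e, tolerance = 1e-12)
  expect_error(fit_calibration(base[1:4, ]), class = "gradfit3d_invalid")
})

test_that("zero position matches a brute-force 0.1 nm scan", {
  ## asymmetric curves so the crossing is away from 0
  tab <- make_width_table(gamma = 200) |>
    dplyr::mutate(wy_px = 1.25 * sqrt(1 + ((z_nm + 150) / 420)^2))
  cal <- suppressWarnings(fit_calibration(tab))
  ## independent dense scan on freshly fitted (unshifted) quartics
  fit4 <- function(y) unname(coef(lm(y ~ poly(tab$z_nm, 4, raw = TRUE))))
  cx <- fit4(tab$wx_px); cy <- fit4(tab$wy_px)
  zg <- seq(-400, 400, by = 0.1)
  z0 <- zg[which.min(abs(quartic_at(cx, zg) - quartic_at(cy, zg)))]
  expect_equal(cal$z_zero, z0, tolerance = 0.05)
})

test_that("non-monotone ellipticity data are rejected with the offending interval", {
  tab <- make_width_table()
  tab$wy_px[3] <- tab$wx_px[3] * 2    # forces an e reversal
  err <- expect_error(fit_calibration(tab),
                      class = "gradfit3d_calibration_rejected")
  expect_match(conditionMessage(err), "not monotone")
  expect_match(conditionMessage(err), "nm")
})

test_that("ellipticity inversion round-trips to better than 0.1 nm", {
  cal <- default_calibration()
  zs <- seq(cal$z_min, cal$z_max, length.out = 81)
  e <- eval_calibration(cal, zs)$e
  inv <- z_from_ellipticity(cal, e)
  expect_true(all(abs(inv$z_nm - zs) < 0.1))
  expect_false(any(inv$range_clipped))
  ## fixed point at z = 0
  e0 <- eval_calibration(cal, 0)$e
  expect_lt(abs(z_from_ellipticity(cal, e0)$z_nm), 0.01)
  ## monotone in e_hat
  zz <- z_from_ellipticity(cal, sort(e))$z_nm
  expect_true(all(diff(zz) > 0))
  ## out-of-range values clamp and flag
  clip <- z_from_ellipticity(cal, c(0.01, 100))
  expect_true(all(clip$range_clipped))
  expect_equal(sort(clip$z_nm), c(cal$z_min, cal$z_max))
  expect_error(z_from_ellipticity(cal, -1), class = "gradfit3d_invalid")
})

test_that("width-based inversions round-trip on noise-free widths", {
  cal <- default_calibration()
  zs <- seq(-380, 380, length.out = 81)
  w <- eval_calibration(cal, zs)
  wd <- z_from_widths_wd(cal, w$w_x, w$w_y)
  expect_true(all(abs(wd$z_nm - zs) < 0.1))
  ## equal widths decode to the zero position
  wz <- eval_calibration(cal, 0)
  expect_lt(abs(z_from_widths_wd(cal, wz$w_x, wz$w_x)$z_nm), 0.5)
  wa <- z_from_widths_wa(cal, w$w_x, w$w_y)
  expect_true(all(abs(wa$z_nm - zs) < 0.1))
  ## width-approximation agrees with an independent 0.01 nm brute scan
  zq <- c(-231.4, 57.9)
  wq <- eval_calibration(cal, zq)
  grid <- seq(cal$z_min, cal$z_max, by = 0.01)
  wg <- eval_calibration(cal, grid)
  for (i in seq_along(zq)) {
    brute <- grid[which.min((wq$w_x[i] - wg$w_x)^2 + (wq$w_y[i] - wg$w_y)^2)]
    expect_equal(z_from_widths_wa(cal, wq$w_x[i], wq$w_y[i])$z_nm, brute,
                 tolerance = 0.1)
  }
  ## continuity under a symmetric perturbation
  d <- seq(-0.02, 0.02, length.out = 9)
  zhat <- z_from_widths_wa(cal, rep(wq$w_x[2], 9), wq$w_y[2] + d)$z_nm
  expect_true(all(abs(diff(zhat)) < 15))
})

test_that("calibration files round-trip byte-identically", {
  cal <- default_calibration()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f1)
  cal2 <- read_calibration(f1)
  write_calibration(cal2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(cal2$coeff_e, cal$coeff_e)
  expect_equal(cal2$z_min, cal$z_min)
})
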