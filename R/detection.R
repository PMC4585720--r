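## Candidate-emitter detection: denoise, local-maximum search with
## non-maximum suppression, ROI extraction.  Detection choices here
## (smoothing sigma, 4-sigma threshold, suppression radius) are this
## package's defaults; fits always run on the raw photon values, the
## smoothed frame is used only to find candidates.

#' Square pixel patch around one candidate emitter
#'
#' @param pixels Square numeric matrix of photon values (side length odd).
#' @param origin `c(row, col)` of the patch's first pixel in the frame,
#'   0-based.
#' @param frame_index Frame the patch came from.
#' @return An object of class `spot_roi`.
#' @export
spot_roi <- function(pixels, origin = c(0L, 0L), frame_index = 1L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels) || nrow(pixels) %% 2 == 0) {
    stop_invalid("ROI must be square with odd side length.")
  }
  structure(
    list(pixels = pixels, origin = as.numeric(origin),
         frame_index = as.integer(frame_index), size = nrow(pixels)),
    class = "spot_roi"
  )
}

#' @export
print.spot_roi <- function(x, ...) {
  cat(sprintf("<spot_roi> %d x %d px at origin (%g, %g), frame %d\n",
              x$size, x$size, x$origin[1], x$origin[2], x$frame_index))
  invisible(x)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

## separable convolution with replicated-edge padding
smooth_separable <- function(frame, k) {
  r <- (length(k) - 1L) / 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  fp <- frame[pad_idx(nrow(frame)), , drop = FALSE]
  out <- matrix(0, nrow(frame), ncol(frame))
  for (i in seq_along(k)) {
    out <- out + k[i] * fp[i:(i + nrow(frame) - 1L), , drop = FALSE]
  }
  op <- out[, pad_idx(ncol(frame)), drop = FALSE]
  out2 <- matrix(0, nrow(frame), ncol(frame))
  for (j in seq_along(k)) {
    out2 <- out2 + k[j] * op[, j:(j + ncol(frame) - 1L), drop = FALSE]
  }
  out2
}

#' Gaussian smoothing for candidate detection
#'
#' @param frame Numeric matrix (photons).
#' @param sigma Smoothing width in pixels (default 1).
#' @return Smoothed matrix of the same size.
#' @export
denoise_frame <- function(frame, sigma = 1) {
  if (length(frame) == 0) stop_invalid("Empty frame.")
  smooth_separable(as.matrix(frame), gaussian_kernel_1d(sigma))
}

#' Find candidate emitters in a smoothed frame
#'
#' Strict local maxima (3 x 3 neighbourhood) above a threshold, followed by
#' non-maximum suppression: candidates are accepted brightest-first and any
#' later candidate within the suppression radius of an accepted one is
#' dropped.  The returned order is row-major (deterministic).
#'
#' @param smoothed Smoothed frame from [denoise_frame()].
#' @param threshold Either an absolute photon threshold, or `NULL` to use
#'   `median(frame) + k * robust sigma` with the median absolute deviation
#'   as the robust background sigma.
#' @param k Threshold multiplier when `threshold` is `NULL` (default 4).
#' @param suppression_radius Minimum separation between candidates in px
#'   (default half the default ROI size, 7.5).
#' @return Integer matrix with columns `row`, `col` (0-based pixel indices).
#' @export
find_candidates <- function(smoothed, threshold = NULL, k = 4,
                            suppression_radius = 7.5) {
  f <- as.matrix(smoothed)
  if (is.null(threshold)) {
    threshold <- median(f) + k * mad(f)
  }
  nr <- nrow(f); nc <- ncol(f)
  inner <- f[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  is_max <- inner > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max &
      (inner > f[2:(nr - 1) + di, 2:(nc - 1) + dj, drop = FALSE])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  cand <- cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)  # frame indices (1-based)
  vals <- f[cand]
  ord <- order(-vals)
  keep <- logical(nrow(cand))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (sum((cand[i, ] - cand[j, ])^2) < suppression_radius^2) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE] - 1L   # back to 0-based
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Extract square ROIs around candidates
#'
#' Candidates closer than `size / 2` to a frame edge are dropped; the count
#' of dropped candidates is attached as the `n_dropped` attribute.
#'
#' @param frame Raw photon frame (fits run on raw values).
#' @param candidates Matrix from [find_candidates()] (0-based `row`, `col`).
#' @param size Odd ROI side length (default 15).
#' @param frame_index Frame number recorded in each ROI.
#' @return List of [spot_roi()] objects.
#' @export
extract_rois <- function(frame, candidates, size = 15L, frame_index = 1L) {
  size <- as.integer(size)
  if (size %% 2 == 0) stop_invalid("ROI size must be odd.")
  half <- size %/% 2
  frame <- as.matrix(frame)
  rois <- list()
  dropped <- 0L
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, 1]; c <- candidates[i, 2]
    if (r - half < 0 || c - half < 0 ||
        r + half > nrow(frame) - 1 || c + half > ncol(frame) - 1) {
      dropped <- dropped + 1L
      next
    }
    rois[[length(rois) + 1L]] <- spot_roi(
      frame[(r - half):(r + half) + 1L, (c - half):(c + half) + 1L],
      origin = c(r - half, c - half), frame_index = frame_index)
  }
  attr(rois, "n_dropped") <- dropped
  rois
}
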