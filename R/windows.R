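#' Walsh function sampled on a length-N grid
#'
#' Walsh functions are the +/-1-valued orthogonal family on \[0,1) indexed by
#' sequency (number of sign changes).  Order `n` is evaluated through its
#' Gray code `g = n XOR (n >> 1)` as the product over the four Gray bits of
#' `sign(sin(2^(i+1) * pi * x))^g_i`.  Samples are taken at
#' `x = (j + 0.5)/N` so that no sample falls on a jump point.
#'
#' @param n order, an integer in 0..15 (four Gray bits).
#' @param N number of samples, at least 8.
#' @return numeric vector of +/-1 values of length `N`.
#' @seealso [smooth_walsh_window()], [walsh_window_bank()]
#' @export
#' @examples
#' walsh_function(1, 8)   # 1 1 1 1 -1 -1 -1 -1
walsh_function <- function(n, N) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 0 || n > 15)
    stop("`n` must be a single integer in 0..15")
  if (!is.numeric(N) || length(N) != 1 || N < 8)
    stop("`N` must be a single integer >= 8")
  g <- bitwXor(as.integer(n), bitwShiftR(as.integer(n), 1L))
  x <- (seq_len(N) - 0.5) / N
  v <- rep(1, N)
  for (i in 0:3) {
    if (bitwAnd(bitwShiftR(g, i), 1L) == 1L)
      v <- v * sign(sin(2^(i + 1) * pi * x))
  }
  v
}

# evaluate the ideal (continuous-argument) Walsh function at points x in [0,1)
walsh_point <- function(n, x) {
  g <- bitwXor(as.integer(n), bitwShiftR(as.integer(n), 1L))
  v <- rep(1, length(x))
  for (i in 0:3) {
    if (bitwAnd(bitwShiftR(g, i), 1L) == 1L)
      v <- v * sign(sin(2^(i + 1) * pi * x))
  }
  v
}

#' Jump positions of a Walsh function
#'
#' Interior discontinuities of order `n`, located analytically: a candidate
#' `x = k/16` is a jump iff an odd number of active Gray-bit factors changes
#' sign there.  Returned in sample units (multiples of `N`).
#'
#' @inheritParams walsh_function
#' @return numeric vector of jump positions in sample units (possibly empty).
#' @export
walsh_jump_points <- function(n, N) {
  g <- bitwXor(as.integer(n), bitwShiftR(as.integer(n), 1L))
  ps <- c()
  for (k in 1:15) {
    x <- k / 16
    nflip <- 0L
    for (i in 0:3) {
      if (bitwAnd(bitwShiftR(g, i), 1L) == 1L &&
          abs(x * 2^(i + 1) - round(x * 2^(i + 1))) < 1e-12)
        nflip <- nflip + 1L
    }
    if (nflip %% 2L == 1L) ps <- c(ps, x * N)
  }
  ps
}

#' Smoothed Walsh window
#'
#' Replaces each +/-1 jump of the Walsh function by an arctangent ramp: for
#' samples with `|x - p_m| < alpha * N` the window is
#' `s_m * (2/pi) * atan(beta * (x - p_m) / (alpha * N))`, where `s_m` is +1
#' for a rising and -1 for a falling jump, so the ramp passes exactly
#' through 0 at the jump.  Outside all transition regions the window equals
#' [walsh_function()].  The `(2/pi)` normalisation keeps the ramp inside
#' (-1, 1); as a consequence the window is discontinuous by
#' `1 - (2/pi) * atan(beta)` at each region edge unless `continuous = TRUE`,
#' which rescales the ramp so the edges meet +/-1.
#'
#' @inheritParams walsh_function
#' @param alpha transition half-width as a fraction of `N`, in (0, 0.25).
#' @param beta arctangent steepness.
#' @param continuous rescale the ramp so it reaches +/-1 at the region edges.
#' @return numeric window of length `N` with values in \[-1, 1\].
#' @export
#' @examples
#' w <- smooth_walsh_window(2, 512)
#' range(w)
smooth_walsh_window <- function(n, N, alpha = 0.01, beta = 2,
                                continuous = FALSE) {
  if (alpha <= 0 || alpha >= 0.25) stop("`alpha` must be in (0, 0.25)")
  if (beta <= 0) stop("`beta` must be positive")
  w <- walsh_function(n, N)
  ps <- walsh_jump_points(n, N)
  if (length(ps) > 1 && min(diff(sort(ps))) <= 2 * alpha * N)
    stop("transition regions of adjacent jumps overlap; reduce `alpha`")
  xs <- seq_len(N) - 0.5
  scale <- if (continuous) 1 / ((2 / pi) * atan(beta)) else 1
  for (p in ps) {
    idx <- which(xs > p - alpha * N & xs < p + alpha * N)
    if (!length(idx)) next
    s <- walsh_point(n, (p + alpha * N * 0.5) / N)  # sign after the jump
    w[idx] <- s * scale * (2 / pi) * atan(beta * (xs[idx] - p) / (alpha * N))
  }
  w
}

new_window_bank <- function(kind, windows, orders = NULL, alpha = NA_real_,
                            beta = NA_real_) {
  structure(list(kind = kind, windows = windows, orders = orders,
                 alpha = alpha, beta = beta, N = ncol(windows)),
            class = "window_bank")
}

#' Walsh window bank
#'
#' Stacks raw or smoothed Walsh windows of the requested orders into a bank
#' for split-spectrum flow computation.  The default orders 1..3 are the
#' second, third and fourth Walsh functions (the first, order 0, is all
#' ones and carries no spectral split).
#'
#' @param orders integer vector of Walsh orders.
#' @param N spectral length.
#' @param smoothed use [smooth_walsh_window()] (default) or the raw +/-1
#'   [walsh_function()].
#' @inheritParams smooth_walsh_window
#' @return a `window_bank` object: list with `kind`
#'   (`"walsh_smoothed"`/`"walsh_raw"`/`"gaussian"`), `windows` (M x N
#'   matrix), `orders`, `alpha`, `beta`, `N`.
#' @export
walsh_window_bank <- function(orders = 1:3, N = 512, smoothed = TRUE,
                              alpha = 0.01, beta = 2, continuous = FALSE) {
  win <- if (smoothed) {
    t(vapply(orders, smooth_walsh_window, numeric(N), N = N,
             alpha = alpha, beta = beta, continuous = continuous))
  } else {
    t(vapply(orders, walsh_function, numeric(N), N = N))
  }
  new_window_bank(if (smoothed) "walsh_smoothed" else "walsh_raw",
                  win, orders = orders,
                  alpha = if (smoothed) alpha else NA_real_,
                  beta = if (smoothed) beta else NA_real_)
}

#' Gaussian window bank
#'
#' `M` unit-peak Gaussians with centres evenly spaced so the first and last
#' sit half a spacing inside the band, as used by the SSADA baseline.
#'
#' @param M number of windows.
#' @param fwhm_fraction full width at half maximum as a fraction of the
#'   spectral length.
#' @param N spectral length.
#' @return a `window_bank` of kind `"gaussian"`.
#' @export
#' @examples
#' bank <- gaussian_window_bank(11, 0.15, 256)
#' dim(bank$windows)
gaussian_window_bank <- function(M, fwhm_fraction, N) {
  stopifnot(M >= 1, fwhm_fraction > 0, fwhm_fraction < 1)
  sigma <- fwhm_fraction * N / (2 * sqrt(2 * log(2)))
  centers <- (seq_len(M) - 0.5) * N / M
  k <- seq_len(N) - 1
  win <- t(vapply(centers, function(c0) exp(-(k - c0)^2 / (2 * sigma^2)),
                  numeric(N)))
  new_window_bank("gaussian", win)
}

#' @export
print.window_bank <- function(x, ...) {
  cat(sprintf("<window_bank> kind=%s, M=%d windows of length N=%d\n",
              x$kind, nrow(x$windows), x$N))
  if (!is.null(x$orders)) cat("  orders:", paste(x$orders, collapse = ", "), "\n")
  if (!is.na(x$alpha)) cat(sprintf("  alpha=%g, beta=%g\n", x$alpha, x$beta))
  invisible(x)
}

#' Export a window bank to CSV
#'
#' One row per window, for inspection in external tools.
#' @param bank a `window_bank`.
#' @param path output file.
#' @export
write_window_bank_csv <- function(bank, path) {
  utils::write.table(bank$windows, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Axial point-spread diagnostics of a spectral window
#'
#' Multiplies the window by a cosine fringe, takes the power spectrum on
#' the positive-frequency half, and summarises the main lobe: the
#' contiguous run of bins above half maximum around the global peak.
#' Reports the full width at half maximum (linear interpolation at the half
#' maximum) and the fraction of spectral energy outside the main lobe, an
#' operational measure of spectral leakage.
#'
#' @param window numeric window, length >= 64.
#' @param fringe_depth_bin fringe frequency in FFT bins (default `N/8`).
#' @return a `psf_report`: list with `fwhm_bins` and
#'   `sidelobe_energy_fraction`.
#' @export
#' @examples
#' psf_report(smooth_walsh_window(2, 512))$sidelobe_energy_fraction
psf_report <- function(window, fringe_depth_bin = length(window) / 8) {
  N <- length(window)
  if (N < 64) stop("window length must be >= 64")
  if (all(window == 0)) stop("all-zero window has no point-spread function")
  t <- (seq_len(N) - 1) / N
  sp <- abs(stats::fft(window * cos(2 * pi * fringe_depth_bin * t)))^2
  sp <- sp[1:(N %/% 2 + 1)]
  pk <- which.max(sp)
  hm <- sp[pk] / 2
  lo <- pk; while (lo > 1 && sp[lo - 1] >= hm) lo <- lo - 1
  hi <- pk; while (hi < length(sp) && sp[hi + 1] >= hm) hi <- hi + 1
  # linear interpolation of the half-max crossings
  left <- if (lo > 1) (lo - 1) + (sp[lo - 1] - hm) / (sp[lo - 1] - sp[lo]) else lo - 1
  right <- if (hi < length(sp)) (hi - 1) + (sp[hi] - hm) / (sp[hi] - sp[hi + 1]) else hi - 1
  structure(list(fwhm_bins = right - left,
                 sidelobe_energy_fraction = 1 - sum(sp[lo:hi]) / sum(sp)),
            class = "psf_report")
}

#' @export
print.psf_report <- function(x, ...) {
  cat(sprintf("<psf_report> FWHM %.2f bins, sidelobe energy fraction %.4f\n",
              x$fwhm_bins, x$sidelobe_energy_fraction))
  invisible(x)
}
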