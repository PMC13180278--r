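#' Preprocess raw spectra: background subtraction and k-linearisation
#'
#' The background of each B-scan position is the mean spectrum over the
#' fast axis of the repeat-averaged interferograms; it is subtracted from
#' every A-line of every repeat.  Estimating the background on the repeat
#' average keeps it strictly static, so the subtraction cannot inject
#' repeat-to-repeat differences into static A-lines.  The spectra are then
#' linearly interpolated onto a uniform wavenumber grid; when `k_grid` is
#' already uniform the interpolation is the identity.
#'
#' @param vol a `spectral_volume` (see [make_spectral_phantom()]).
#' @return a `spectral_volume` with background-free, k-linear spectra.
#' @export
preprocess_spectra <- function(vol) {
  stopifnot(inherits(vol, "spectral_volume"))
  k <- vol$k_grid
  if (any(diff(k) <= 0)) stop("`k_grid` must be strictly increasing")
  d <- dim(vol$data)
  n_rep <- d[1]; n_y <- d[2]; n_x <- d[3]; n_k <- d[4]
  if (n_x < 8) stop("need at least 8 A-scans per B-scan")
  av <- apply(vol$data, c(2, 3, 4), mean)           # [y, x, k]
  bg <- apply(av, c(1, 3), mean)                    # [y, k]
  bg_arr <- aperm(array(bg, c(n_y, n_k, n_x)), c(1, 3, 2))  # [y, x, k]
  out <- vol$data
  for (r in seq_len(n_rep))
    out[r, , , ] <- slice_repeat(out, r) - bg_arr
  # k-linearisation
  uni <- seq(k[1], k[length(k)], length.out = length(k))
  if (max(abs(uni - k)) > 1e-12 * diff(range(k))) {
    flat <- matrix(aperm(out, c(4, 1, 2, 3)), n_k)
    flat <- apply(flat, 2, function(s) stats::approx(k, s, xout = uni,
                                                     rule = 2)$y)
    out <- aperm(array(flat, c(n_k, n_rep, n_y, n_x)), c(2, 3, 4, 1))
  }
  structure(list(data = out, k_grid = uni, meta = vol$meta),
            class = "spectral_volume")
}

#' Reconstruct depth-resolved complex signals
#'
#' Multiplies every A-line by a spectral window, Fourier transforms along
#' k, and keeps the positive-frequency half (the DC bin is dropped), so the
#' depth axis has `n_k / 2` bins.
#'
#' @param vol a preprocessed `spectral_volume`.
#' @param window numeric window of length `n_k`.
#' @return a `complex_volume`: `data` array \[repeat, y, x, z\] of complex
#'   values plus the `provenance` window description.
#' @export
reconstruct_complex <- function(vol, window) {
  stopifnot(inherits(vol, "spectral_volume"))
  d <- dim(vol$data)
  n_rep <- d[1]; n_y <- d[2]; n_x <- d[3]; n_k <- d[4]
  if (length(window) != n_k)
    stop(sprintf("window length %d does not match n_k = %d",
                 length(window), n_k))
  n_z <- n_k %/% 2L
  out <- array(0i, c(n_rep, n_y, n_x, n_z))
  for (r in seq_len(n_rep)) {
    S <- matrix(aperm(slice_repeat(vol$data, r), c(3, 2, 1)), n_k)  # [k, x*y]
    F <- stats::mvfft(window * S)[2:(n_z + 1), , drop = FALSE]
    out[r, , , ] <- aperm(array(F, c(n_z, n_x, n_y)), c(3, 2, 1))
  }
  structure(list(data = out, z_pitch = 1, provenance = deparse(substitute(window))),
            class = "complex_volume")
}

#' Amplitude of a complex volume
#'
#' @param cvol a `complex_volume`.
#' @return an `amplitude_volume` with non-negative `data` of the same shape.
#' @export
amplitude_volume <- function(cvol) {
  stopifnot(inherits(cvol, "complex_volume"))
  structure(list(data = abs(cvol$data), provenance = cvol$provenance),
            class = "amplitude_volume")
}

#' Simplified bulk-phase compensation
#'
#' For each consecutive repeat pair and each A-line, the amplitude-weighted
#' mean phase difference `Arg(sum(E_{n+1} * Conj(E_n)))` is removed from the
#' later repeat.  Amplitudes are untouched up to floating-point rotation
#' round-off (one ulp); all-zero A-lines pass through unchanged.  This is a deliberately simple stand-in for full per-depth
#' phase registration; on phantoms without bulk motion it is exact.
#'
#' @param cvol a `complex_volume` with at least 2 repeats.
#' @return the phase-aligned `complex_volume`.
#' @export
compensate_bulk_phase <- function(cvol) {
  stopifnot(inherits(cvol, "complex_volume"))
  d <- dim(cvol$data)
  if (d[1] < 2) stop("bulk-phase compensation needs n_repeat >= 2")
  out <- cvol$data
  n_z <- d[4]
  for (r in seq_len(d[1] - 1)) {
    e_next <- slice_repeat(out, r + 1)
    prod <- e_next * Conj(slice_repeat(out, r))
    w <- apply(prod, c(1, 2), sum)               # [y, x]
    ph <- Arg(w)
    ph[Mod(w) == 0] <- 0
    out[r + 1, , , ] <- e_next * exp(-1i * array(rep(ph, n_z), d[2:4]))
  }
  structure(list(data = out, z_pitch = cvol$z_pitch,
                 provenance = cvol$provenance),
            class = "complex_volume")
}

#' @export
print.complex_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<complex_volume> %d repeats x %d y x %d x x %d z-bins\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' @export
print.amplitude_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<amplitude_volume> %d repeats x %d y x %d x x %d z-bins\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
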