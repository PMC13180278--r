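new_flow_volume <- function(data, method, n_repeat, n_splits = 1L) {
  structure(list(data = data, method = method, n_repeat = n_repeat,
                 n_splits = n_splits), class = "flow_volume")
}

#' @export
print.flow_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flow_volume> method=%s, %d y x %d x x %d z-bins (N=%d, M=%d)\n",
              x$method, d[1], d[2], d[3], x$n_repeat, x$n_splits))
  invisible(x)
}

amp_array <- function(amps) {
  if (inherits(amps, "amplitude_volume")) amps$data else amps
}

#' Improved speckle-contrast (ISCA) flow signal
#'
#' Voxelwise
#' `I_flow = 1/(N-1) * 1/N * sum_n |A_{n+1} - A_n| / (A_{n+1} A_n) * sum_n A_n`
#' over the `N` repeats.  The amplitude product in the denominator is
#' guarded by `eps = 1e-12 * max(A)^2` so that zero amplitudes stay finite.
#'
#' @param amps an `amplitude_volume` or a numeric array
#'   \[repeat, y, x, z\] with `N >= 2` repeats.
#' @return a `flow_volume` with non-negative `data` \[y, x, z\].
#' @export
#' @examples
#' a <- array(c(1, 3), c(2, 1, 1, 1))
#' isca_flow(a)$data        # 4/3
isca_flow <- function(amps) {
  A <- amp_array(amps)
  N <- dim(A)[1]
  if (is.null(N) || N < 2) stop("ISCA needs n_repeat >= 2")
  if (any(A < 0)) stop("amplitudes must be non-negative")
  eps <- 1e-12 * max(A)^2
  num <- 0; tot <- 0
  for (n in seq_len(N - 1)) {
    a1 <- slice_repeat(A, n)
    a2 <- slice_repeat(A, n + 1)
    num <- num + abs(a2 - a1) / pmax(a2 * a1, eps)
  }
  for (n in seq_len(N)) tot <- tot + slice_repeat(A, n)
  out <- (1 / (N - 1)) * (1 / N) * num * tot
  dim(out) <- dim(A)[-1]
  new_flow_volume(out, "isca", N)
}

#' Split-spectrum amplitude-decorrelation (SSADA)
#'
#' `D = 1 - 1/(N-1) * 1/M * sum_n sum_m A_{m,n} A_{m,n+1} /
#' ((A_{m,n}^2 + A_{m,n+1}^2)/2)`, averaged over `M` spectral splits and
#' `N-1` repeat pairs; values are clipped to \[0,1\] only to absorb
#' floating-point round-off.
#'
#' @param split_amps list of `M >= 1` amplitude volumes (one per spectral
#'   split), identical shapes, each with `N >= 2` repeats.
#' @return a `flow_volume` with `data` in \[0,1\].
#' @export
#' @examples
#' a <- array(c(1, 3), c(2, 1, 1, 1))
#' ssada_decorrelation(list(a))$data    # 0.4
ssada_decorrelation <- function(split_amps) {
  if (!is.list(split_amps)) split_amps <- list(split_amps)
  arrs <- lapply(split_amps, amp_array)
  M <- length(arrs)
  dims <- lapply(arrs, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all spectral splits must share one shape")
  N <- dims[[1]][1]
  if (N < 2) stop("SSADA needs n_repeat >= 2")
  acc <- 0
  for (A in arrs) {
    for (n in seq_len(N - 1)) {
      a1 <- slice_repeat(A, n)
      a2 <- slice_repeat(A, n + 1)
      den <- (a1^2 + a2^2) / 2
      corr <- a1 * a2 / den
      corr[den == 0] <- 1          # two zero amplitudes: perfectly correlated
      acc <- acc + (1 - corr)
    }
  }
  out <- pmin(pmax(acc / ((N - 1) * M), 0), 1)
  dim(out) <- dims[[1]][-1]
  new_flow_volume(out, "ssada", N, n_splits = M)
}

#' Amplitude OMAG flow signal
#'
#' Canonical mean absolute inter-repeat amplitude difference,
#' `1/(N-1) * sum_n |A_{n+1} - A_n|`.
#'
#' @inheritParams isca_flow
#' @return a `flow_volume`.
#' @export
omag_amplitude <- function(amps) {
  A <- amp_array(amps)
  N <- dim(A)[1]
  if (is.null(N) || N < 2) stop("OMAG needs n_repeat >= 2")
  acc <- 0
  for (n in seq_len(N - 1))
    acc <- acc + abs(slice_repeat(A, n + 1) - slice_repeat(A, n))
  out <- acc / (N - 1)
  dim(out) <- dim(A)[-1]
  new_flow_volume(out, "omag_a", N)
}

#' Complex OMAG flow signal
#'
#' Mean absolute inter-repeat complex difference
#' `1/(N-1) * sum_n |E_{n+1} - E_n|` on bulk-phase-compensated signals.
#'
#' @param cvol a `complex_volume`; run [compensate_bulk_phase()] first.
#' @return a `flow_volume`.
#' @export
omag_complex <- function(cvol) {
  stopifnot(inherits(cvol, "complex_volume"))
  E <- cvol$data
  N <- dim(E)[1]
  if (N < 2) stop("OMAG needs n_repeat >= 2")
  acc <- 0
  for (n in seq_len(N - 1))
    acc <- acc + Mod(slice_repeat(E, n + 1) - slice_repeat(E, n))
  out <- acc / (N - 1)
  dim(out) <- dim(E)[-1]
  new_flow_volume(out, "omag_c", N)
}

#' Split-spectrum flow computation
#'
#' Runs the full flow front-end: preprocessing, one reconstruction per
#' window of the bank (with bulk-phase compensation), a per-split flow
#' signal, and the equal-weight average over splits.
#'
#' @param vol a raw `spectral_volume`.
#' @param bank a `window_bank` ([walsh_window_bank()],
#'   [gaussian_window_bank()]).
#' @param method `"isca"` (per-split speckle contrast, the proposed method
#'   with a smoothed Walsh bank) or `"ssada"` (split-spectrum
#'   decorrelation).
#' @param compensate apply [compensate_bulk_phase()] before taking
#'   amplitudes.
#' @return a `flow_volume` with `method` tagged
#'   `"<method>_<bank kind>"`.
#' @export
split_spectrum_flow <- function(vol, bank, method = c("isca", "ssada"),
                                compensate = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(bank, "window_bank"))
  pre <- preprocess_spectra(vol)
  amps <- lapply(seq_len(nrow(bank$windows)), function(m) {
    cv <- reconstruct_complex(pre, bank$windows[m, ])
    if (compensate) cv <- compensate_bulk_phase(cv)
    amplitude_volume(cv)$data
  })
  N <- dim(amps[[1]])[1]
  M <- length(amps)
  if (method == "ssada") {
    fv <- ssada_decorrelation(amps)
  } else {
    acc <- 0
    for (A in amps) acc <- acc + isca_flow(A)$data
    fv <- new_flow_volume(acc / M, "isca", N, n_splits = M)
  }
  fv$n_splits <- M
  fv$method <- paste0(method, "_", bank$kind)
  fv
}
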