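#' @title Binary-image and histogram primitives
#' @description
#' Small, dependency-free image operations used throughout the package:
#' reflect padding, box sums via summed-area tables, separable Gaussian
#' smoothing, Otsu thresholding on a 256-bin histogram, disk structuring
#' elements with erosion/dilation/opening/closing, 8-connected component
#' labelling, Zhang-Suen thinning, and sub-pixel marching-squares contour
#' length.
#' @name morphology
#' @keywords internal
NULL

pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r < nr, r < nc)
  ri <- c((r + 1):2, 1:nr, (nr - 1):(nr - r))
  ci <- c((r + 1):2, 1:nc, (nc - 1):(nc - r))
  m[ri, ci, drop = FALSE]
}

# Sum over centred (2r+1)x(2r+1) windows, reflect-padded at the borders.
box_sum <- function(m, r) {
  p <- pad_reflect(m, r)
  cs <- rbind(0, apply(p, 2, cumsum))
  v <- cs[(2 * r + 2):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - 2 * r - 1), , drop = FALSE]
  cs2 <- cbind(0, t(apply(v, 1, cumsum)))
  cs2[, (2 * r + 2):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - 2 * r - 1), drop = FALSE]
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  p <- pad_reflect(m, r)
  p <- apply(p, 2, function(v) stats::filter(v, k, sides = 2))
  p <- t(apply(t(p), 2, function(v) stats::filter(v, k, sides = 2)))
  p[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

#' Otsu threshold of a numeric sample
#'
#' Classical Otsu threshold maximising between-class variance on a 256-bin
#' histogram.  The histogram spans `[min(x), hi]`; values above `hi` are
#' counted in the top bin, which makes the binning robust to the long right
#' tails of ratio-type flow signals (set `hi = max(x)` for the textbook
#' behaviour).
#'
#' @param x numeric vector (finite values).
#' @param hi upper edge of the histogram; defaults to `max(x)`.
#' @return the threshold, in the units of `x`.  For a constant sample the
#'   common value is returned.
#' @export
#' @examples
#' otsu_threshold(c(rnorm(100, 1), rnorm(100, 9)))
otsu_threshold <- function(x, hi = max(x)) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  lo <- min(x)
  if (hi <= lo) return(lo)
  bins <- pmin(256L, pmax(1L, floor((x - lo) / (hi - lo) * 256) + 1L))
  h <- as.numeric(tabulate(bins, 256L))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256L))
  wt <- w[256L]; mt <- mu[256L]
  sb <- (mt * w - mu * wt)^2 / (w * (wt - w))
  sb[!is.finite(sb)] <- -Inf
  lo + which.max(sb) / 256 * (hi - lo)
}

#' Disk structuring element
#'
#' @param r radius in pixels; `disk_element(1)` is the 3x3 cross.
#' @return binary matrix of odd dimension.
#' @export
disk_element <- function(r) {
  d <- 2L * ceiling(r) + 1L
  c0 <- ceiling(r) + 1L
  ij <- expand.grid(i = 1:d, j = 1:d)
  matrix(as.integer((ij$i - c0)^2 + (ij$j - c0)^2 <= r^2), d, d)
}

shift_pad <- function(m, di, dj, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(fill, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
}

kernel_shifts <- function(kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  w <- which(kernel == 1L, arr.ind = TRUE)
  cbind(di = w[, 1] - r - 1L, dj = w[, 2] - r - 1L)
}

apply_kernel <- function(m, kernel, combine, fill) {
  sh <- kernel_shifts(kernel)
  nr <- nrow(m); nc <- ncol(m)
  r <- max(abs(sh))
  p <- matrix(fill, nr + 2L * r, nc + 2L * r)
  p[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  out <- NULL
  for (s in seq_len(nrow(sh))) {
    q <- p[(r + 1 + sh[s, 1]):(r + nr + sh[s, 1]),
           (r + 1 + sh[s, 2]):(r + nc + sh[s, 2]), drop = FALSE]
    out <- if (is.null(out)) q else combine(out, q)
  }
  out
}

#' Binary erosion, dilation, opening and closing
#'
#' @param m binary matrix (logical or 0/1).
#' @param kernel structuring element, e.g. [disk_element()].
#' @return integer 0/1 matrix of the same shape.
#' @export
erode_mask <- function(m, kernel = disk_element(1)) {
  storage.mode(m) <- "integer"
  apply_kernel(m, kernel, function(a, b) a & b, fill = 1L) * 1L
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(m, kernel = disk_element(1)) {
  storage.mode(m) <- "integer"
  apply_kernel(m, kernel, function(a, b) a | b, fill = 0L) * 1L
}

#' @rdname erode_mask
#' @export
open_mask <- function(m, kernel = disk_element(1)) {
  dilate_mask(erode_mask(m, kernel), kernel)
}

#' @rdname erode_mask
#' @export
close_mask <- function(m, kernel = disk_element(1)) {
  erode_mask(dilate_mask(m, kernel), kernel)
}

#' Label 8-connected components
#'
#' Iterative maximum-label propagation over the 8-neighbourhood; exact and
#' adequate for the image sizes this package works at.
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 for background, components numbered from 1 in
#'   decreasing size order.
#' @export
label_components <- function(mask) {
  mask <- mask & !is.na(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  repeat {
    old <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      q <- shift_pad(lab, di, dj)
      w <- q > lab & mask
      lab[w] <- q[w]
    }
    if (identical(lab, old)) break
  }
  # renumber by decreasing size
  sz <- sort(table(lab[lab > 0L]), decreasing = TRUE)
  ren <- integer(max(lab))
  ren[as.integer(names(sz))] <- seq_along(sz)
  lab[lab > 0L] <- ren[lab[lab > 0L]]
  lab
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Zhang-Suen thinning.  Every skeleton pixel retains 8-connectivity of the
#' original component.
#'
#' @param m binary matrix.
#' @return integer 0/1 skeleton matrix.
#' @export
thin_skeleton <- function(m) {
  m <- (m > 0) * 1L
  repeat {
    changed <- 0L
    for (step in 0:1) {
      P2 <- shift_pad(m, -1L, 0L); P3 <- shift_pad(m, -1L, 1L)
      P4 <- shift_pad(m, 0L, 1L);  P5 <- shift_pad(m, 1L, 1L)
      P6 <- shift_pad(m, 1L, 0L);  P7 <- shift_pad(m, 1L, -1L)
      P8 <- shift_pad(m, 0L, -1L); P9 <- shift_pad(m, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      sq <- cbind(c(P2), c(P3), c(P4), c(P5), c(P6), c(P7), c(P8), c(P9), c(P2))
      A <- matrix(rowSums(sq[, 1:8, drop = FALSE] == 0L &
                          sq[, 2:9, drop = FALSE] == 1L), nrow(m), ncol(m))
      cond <- if (step == 0L) {
        (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      changed <- changed + sum(del)
      m[del] <- 0L
    }
    if (changed == 0L) break
  }
  m
}

#' Sub-pixel contour length of a binary mask
#'
#' The mask is lightly Gaussian-smoothed and the 0.5 iso-contour is traced
#' with linearly interpolated marching squares; the summed segment length is
#' returned in pixel units.  The smoothing (default sigma 1.5 px) removes
#' pixelation so that a digital disc measures its true circumference to
#' within a few tenths of a percent.
#'
#' @param mask logical matrix.
#' @param sigma smoothing standard deviation in pixels.
#' @return contour length in pixels.
#' @export
contour_length <- function(mask, sigma = 1.5) {
  f <- gauss_smooth(mask * 1, sigma) - 0.5
  nr <- nrow(f); nc <- ncol(f)
  TL <- f[-nr, -nc]; TR <- f[-nr, -1]; BR <- f[-1, -1]; BL <- f[-1, -nc]
  cross <- function(a, b) ifelse((a > 0) != (b > 0), a / (a - b), NA_real_)
  top <- cross(TL, TR); right <- cross(TR, BR)
  bottom <- cross(BL, BR); left <- cross(TL, BL)
  idx <- (TL > 0) * 8 + (TR > 0) * 4 + (BR > 0) * 2 + (BL > 0) * 1
  seg <- function(x1, y1, x2, y2) {
    s <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
    s[is.na(s)] <- 0
    s
  }
  Z <- TL * 0; O <- Z + 1
  L <- Z
  add <- function(L, cases, x1, y1, x2, y2) {
    sel <- idx %in% cases
    L[sel] <- L[sel] + seg(x1, y1, x2, y2)[sel]
    L
  }
  # corner points: top (top,0), right (1,right), bottom (bottom,1), left (0,left)
  L <- add(L, c(8, 7), Z, left, top, Z)
  L <- add(L, c(4, 11), top, Z, O, right)
  L <- add(L, c(2, 13), O, right, bottom, O)
  L <- add(L, c(1, 14), bottom, O, Z, left)
  L <- add(L, c(12, 3), Z, left, O, right)
  L <- add(L, c(9, 6), top, Z, bottom, O)
  L <- add(L, 10, Z, left, top, Z)
  L <- add(L, 10, O, right, bottom, O)
  L <- add(L, 5, top, Z, O, right)
  L <- add(L, 5, bottom, O, Z, left)
  sum(L)
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# extract repeat r of a [repeat, ...] array, preserving the trailing dims
slice_repeat <- function(A, r) {
  d <- dim(A)
  array(A[r, , , ], d[-1])
}
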