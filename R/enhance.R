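#' Average repeated B-scans into a structural volume
#'
#' @param amps an `amplitude_volume` or array \[repeat, y, x, z\], `N >= 1`.
#' @return numeric array \[y, x, z\], the mean across repeats.
#' @export
average_structural <- function(amps) {
  A <- amp_array(amps)
  out <- apply(A, c(2, 3, 4), mean)
  out
}

#' Layer boundaries container
#'
#' @param surfaces named list, in anatomical order, of integer depth-index
#'   matrices \[y, x\] (one per surface).
#' @param source one of `"phantom_truth"`, `"gradient_fallback"`,
#'   `"external"`.
#' @return a `layer_boundaries` object.
#' @export
layer_boundaries <- function(surfaces, source = c("external", "phantom_truth",
                                                  "gradient_fallback")) {
  source <- match.arg(source)
  stopifnot(is.list(surfaces), !is.null(names(surfaces)))
  if (length(surfaces) >= 2) {
    for (s in seq_len(length(surfaces) - 1)) {
      if (any(surfaces[[s + 1]] <= surfaces[[s]]))
        stop(sprintf("surface `%s` is not strictly below `%s` everywhere",
                     names(surfaces)[s + 1], names(surfaces)[s]))
    }
  }
  structure(list(surfaces = surfaces, source = source),
            class = "layer_boundaries")
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat(sprintf("<layer_boundaries> %d surfaces (%s): %s\n",
              length(x$surfaces), x$source,
              paste(names(x$surfaces), collapse = " > ")))
  invisible(x)
}

#' Slab between two layer surfaces
#'
#' @param name slab label, e.g. `"IR"` or `"MR"`.
#' @param top_surface,bottom_surface surface names present in the
#'   `layer_boundaries` the slab will be applied to.
#' @return a `slab_spec` object.
#' @export
slab_spec <- function(name, top_surface, bottom_surface) {
  structure(list(name = name, top_surface = top_surface,
                 bottom_surface = bottom_surface), class = "slab_spec")
}

running_median3 <- function(m) {
  # lateral 3-point median along each row direction of a [y, x] matrix
  nr <- nrow(m); nc <- ncol(m)
  if (nc < 3) return(m)
  left <- cbind(m[, 1], m[, -nc])
  right <- cbind(m[, -1], m[, nc])
  arr <- array(c(left, m, right), c(nr, nc, 3))
  apply(arr, c(1, 2), stats::median)
}

#' Detect layer surfaces from a structural volume
#'
#' Fallback layer segmentation for volumes whose layers differ in mean
#' intensity: per A-line the axial intensity profile is smoothed, the
#' `n_surfaces` strongest local maxima of the absolute axial gradient are
#' taken as surface candidates, sorted by depth, median-filtered laterally,
#' and forced into strictly increasing order.
#'
#' @param struct numeric array \[y, x, z\] (see [average_structural()]).
#' @param n_surfaces number of surfaces to locate.
#' @param surface_names names for the detected surfaces.
#' @param smooth_sd axial Gaussian smoothing sd, in bins.
#' @param lateral_halfwidth half-width of the lateral moving average applied
#'   to the B-scan before the gradient search (suppresses speckle).
#' @param min_separation minimum axial distance (bins) between the picked
#'   gradient maxima.
#' @return a `layer_boundaries` with `source = "gradient_fallback"`.
#' @export
segment_layers_fallback <- function(struct, n_surfaces = 4,
                                    surface_names = NULL, smooth_sd = 2,
                                    lateral_halfwidth = 4L,
                                    min_separation = 5L) {
  d <- dim(struct)
  n_y <- d[1]; n_x <- d[2]; n_z <- d[3]
  if (is.null(surface_names))
    surface_names <- paste0("S", seq_len(n_surfaces))
  stopifnot(length(surface_names) == n_surfaces)
  r <- ceiling(3 * smooth_sd)
  kern <- stats::dnorm(-r:r, sd = smooth_sd)
  kern <- kern / sum(kern)
  depth <- array(NA_real_, c(n_y, n_x, n_surfaces))
  for (y in seq_len(n_y)) {
    prof <- matrix(struct[y, , ], n_x, n_z)
    if (lateral_halfwidth > 0) {
      w <- lateral_halfwidth
      idx <- lapply(seq_len(n_x), function(x)
        max(1, x - w):min(n_x, x + w))
      prof <- t(vapply(idx, function(i) colMeans(prof[i, , drop = FALSE]),
                       numeric(n_z)))
    }
    for (x in seq_len(n_x)) {
      p <- as.numeric(stats::filter(c(rep(prof[x, 1], r), prof[x, ],
                                      rep(prof[x, n_z], r)), kern,
                                    sides = 2))[(r + 1):(r + n_z)]
      g <- abs(diff(p))
      left <- c(-Inf, g[-length(g)])
      right <- c(g[-1], -Inf)
      loc <- which(g >= left & g > right & g > 1e-9)
      # greedy pick by magnitude with a minimum axial separation
      ord <- loc[order(g[loc], decreasing = TRUE)]
      top <- c()
      for (cand in ord) {
        if (all(abs(cand - top) >= min_separation)) top <- c(top, cand)
        if (length(top) == n_surfaces) break
      }
      if (length(top) < n_surfaces)
        stop(sprintf(
          "only %d gradient maxima found at (y=%d, x=%d); surfaces missing: %s",
          length(top), y, x,
          paste(surface_names[(length(top) + 1):n_surfaces], collapse = ", ")))
      depth[y, x, ] <- sort(top)
    }
  }
  surfaces <- vector("list", n_surfaces)
  for (s in seq_len(n_surfaces)) {
    m <- running_median3(depth[, , s])
    surfaces[[s]] <- matrix(as.integer(round(m)), n_y, n_x)
  }
  # enforce strict ordering
  for (s in seq_len(n_surfaces - 1)) {
    bad <- surfaces[[s + 1]] <= surfaces[[s]]
    surfaces[[s + 1]][bad] <- surfaces[[s]][bad] + 1L
  }
  names(surfaces) <- surface_names
  layer_boundaries(surfaces, source = "gradient_fallback")
}

retina_mask_from_boundaries <- function(bounds, n_z, n_y, n_x) {
  top <- bounds$surfaces[[1]]
  bot <- bounds$surfaces[[length(bounds$surfaces)]]
  mask <- array(FALSE, c(n_y, n_x, n_z))
  zs <- array(rep(seq_len(n_z), each = n_y * n_x), c(n_y, n_x, n_z))
  mask <- zs > array(rep(top, n_z), c(n_y, n_x, n_z)) &
    zs <= array(rep(bot, n_z), c(n_y, n_x, n_z))
  mask
}

#' Layer-mask assisted Otsu truncation of one flow B-scan
#'
#' The Otsu threshold is computed from the in-mask values only, on a
#' 256-bin histogram whose top edge is the `clip_quantile` of the in-mask
#' values (long right tails of ratio-type flow signals would otherwise
#' compress the histogram; values above the edge count in the top bin).
#' In-mask values below the threshold and all out-of-mask values are set to
#' zero; in-mask values at or above it are kept.  A constant in-mask region
#' is returned unchanged inside the mask (degenerate rule).
#'
#' @param flow_bscan numeric 2-D flow image.
#' @param retina_mask logical matrix of the same shape, non-empty.
#' @param clip_quantile upper histogram edge as a quantile of the in-mask
#'   values; `1` gives the textbook min-max histogram.
#' @return the truncated flow image.
#' @export
enhance_flow_bscan <- function(flow_bscan, retina_mask, clip_quantile = 0.99) {
  if (!all(dim(flow_bscan) == dim(retina_mask)))
    stop("mask shape must match the image")
  if (!any(retina_mask)) stop("retina mask is empty")
  v <- flow_bscan[retina_mask]
  out <- flow_bscan
  out[!retina_mask] <- 0
  if (max(v) <= min(v)) return(out)
  thr <- otsu_threshold(v, hi = stats::quantile(v, clip_quantile))
  out[retina_mask & flow_bscan < thr] <- 0
  out
}

#' Layer-mask assisted Otsu truncation of a flow volume
#'
#' Applies [enhance_flow_bscan()] over a `flow_volume`, with the retina
#' mask derived from the first and last surfaces of `bounds`.  With
#' `scope = "volume"` (default) one Otsu threshold is computed from all
#' in-mask voxels; `scope = "bscan"` thresholds each slow-axis position
#' separately.
#'
#' @param flow a `flow_volume`.
#' @param bounds a `layer_boundaries`.
#' @param scope `"volume"` or `"bscan"`.
#' @inheritParams enhance_flow_bscan
#' @return the enhanced `flow_volume`.
#' @export
enhance_flow_volume <- function(flow, bounds, scope = c("volume", "bscan"),
                                clip_quantile = 0.99) {
  scope <- match.arg(scope)
  stopifnot(inherits(flow, "flow_volume"), inherits(bounds, "layer_boundaries"))
  d <- dim(flow$data)
  mask <- retina_mask_from_boundaries(bounds, n_z = d[3], n_y = d[1], n_x = d[2])
  out <- flow$data
  if (scope == "volume") {
    v <- out[mask]
    out[!mask] <- 0
    if (max(v) > min(v)) {
      thr <- otsu_threshold(v, hi = stats::quantile(v, clip_quantile))
      out[mask & flow$data < thr] <- 0
    }
  } else {
    for (y in seq_len(d[1])) {
      out[y, , ] <- enhance_flow_bscan(matrix(flow$data[y, , ], d[2], d[3]),
                                       matrix(mask[y, , ], d[2], d[3]),
                                       clip_quantile = clip_quantile)
    }
  }
  new_flow_volume(out, paste0(flow$method, "_enhanced"), flow$n_repeat,
                  flow$n_splits)
}

new_angiogram <- function(data, pixel_pitch_mm, slab, method) {
  structure(list(data = data, pixel_pitch_mm = pixel_pitch_mm, slab = slab,
                 method = method), class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %d x %d px, pitch %.4g mm, slab %s, method %s\n",
              nrow(x$data), ncol(x$data), x$pixel_pitch_mm,
              if (inherits(x$slab, "slab_spec")) x$slab$name else as.character(x$slab),
              x$method))
  invisible(x)
}

#' @export
plot.angiogram <- function(x, main = NULL, ...) {
  img <- x$data
  img <- img / max(img, 1e-12)
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(img) / ncol(img),
                  main = main %||% sprintf("%s / %s", x$method,
                    if (inherits(x$slab, "slab_spec")) x$slab$name else x$slab),
                  ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean en face projection of a flow volume over a slab
#'
#' For every lateral position the flow values with depth in
#' `[top_surface, bottom_surface)` (half-open) are averaged.  Positions
#' whose slab is empty project to zero and are counted in a warning.
#'
#' @param flow a `flow_volume`.
#' @param bounds a `layer_boundaries` containing the slab's surfaces.
#' @param slab a [slab_spec()].
#' @param pixel_pitch_mm lateral pitch recorded in the output.
#' @return an `angiogram`.
#' @export
enface_project <- function(flow, bounds, slab, pixel_pitch_mm = NA_real_) {
  stopifnot(inherits(flow, "flow_volume"), inherits(slab, "slab_spec"))
  if (!all(c(slab$top_surface, slab$bottom_surface) %in%
           names(bounds$surfaces)))
    stop("slab surfaces not present in the layer boundaries")
  top <- bounds$surfaces[[slab$top_surface]]
  bot <- bounds$surfaces[[slab$bottom_surface]]
  d <- dim(flow$data)
  if (max(bot) > d[3]) stop("slab extends beyond the volume depth range")
  out <- matrix(0, d[1], d[2])
  n_empty <- 0L
  for (y in seq_len(d[1])) {
    plane <- matrix(flow$data[y, , ], d[2], d[3])
    for (x in seq_len(d[2])) {
      z1 <- top[y, x] + 1L; z2 <- bot[y, x]
      if (z2 < z1) { n_empty <- n_empty + 1L; next }
      out[y, x] <- mean(plane[x, z1:z2])
    }
  }
  if (n_empty > 0)
    warning(sprintf("%d lateral positions had an empty slab; set to 0", n_empty))
  new_angiogram(out, pixel_pitch_mm, slab, flow$method)
}

#' Display normalisation of an angiogram image
#'
#' Percentile contrast stretch to \[0,1\]: the `p_low` quantile maps to 0
#' (black level) and the `p_high` quantile to 1, with clipping — the
#' convention used when angiograms are rendered to 8-bit display images and
#' the scale on which the quality metrics are evaluated.
#'
#' @param a numeric matrix or `angiogram`.
#' @param p_low,p_high black/white-point quantiles.
#' @return matrix (or `angiogram`) with values in \[0,1\].
#' @export
display_normalize <- function(a, p_low = 0.5, p_high = 0.995) {
  if (inherits(a, "angiogram")) {
    a$data <- display_normalize(a$data, p_low, p_high)
    return(a)
  }
  lo <- stats::quantile(a, p_low)
  hi <- stats::quantile(a, p_high)
  if (hi <= lo) return(a * 0)
  pmin(pmax((a - lo) / (hi - lo), 0), 1)
}
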