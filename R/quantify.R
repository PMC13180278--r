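#' Adaptive (local-mean) binarisation
#'
#' A pixel is vessel iff its value exceeds the mean of its
#' `block x block` neighbourhood (reflect-padded) by more than `offset`.
#' Adding a constant to the image leaves the result unchanged.
#'
#' @param img numeric matrix or `angiogram`.
#' @param block odd window size >= 3.
#' @param offset positive margin above the local mean, in image units.
#' @return logical vessel matrix.
#' @export
adaptive_binarize <- function(img, block = 31, offset = 0.02) {
  if (inherits(img, "angiogram")) img <- img$data
  if (block < 3 || block %% 2 == 0) stop("`block` must be an odd integer >= 3")
  r <- (block - 1) / 2
  mu <- box_sum(img, r) / block^2
  img > mu + offset
}

#' Local fractal dimension map
#'
#' Mass-dimension estimate per pixel of a binary vessel map: for each
#' half-width `w` in `w_range` the white pixels in the centred
#' `(2w+1) x (2w+1)` window are counted (reflect-padded) and the
#' least-squares slope of `ln N_s` against `ln(2w+1)` over the scales with
#' `N_s > 0` is taken.  Pixels with fewer than two usable scales get raw
#' value 0; raw slopes are clamped to \[0, 2\] (the dimension of a planar
#' set); the map is then min-max normalised to \[0,1\].
#'
#' @param binary logical vessel matrix (e.g. from [adaptive_binarize()]).
#' @param w_range integer window half-widths, minimum >= 1.
#' @return an `lfd_map`: list with `data` (normalised \[0,1\]), `raw`
#'   (slopes in \[0,2\]) and `w_range`.
#' @export
#' @examples
#' m <- matrix(FALSE, 21, 21); m[11, ] <- TRUE
#' local_fractal_dimension(m)$raw[11, 11]   # 1: a line is one-dimensional
local_fractal_dimension <- function(binary, w_range = 2:6) {
  if (length(w_range) < 1 || min(w_range) < 1)
    stop("`w_range` must be non-empty with minimum >= 1")
  b <- binary * 1
  scales <- 2 * w_range + 1
  lx <- log(scales)
  C <- vapply(w_range, function(w) c(box_sum(b, w)), numeric(length(b)))
  use <- C > 0
  L <- log(pmax(C, 1))
  n <- rowSums(use)
  X <- matrix(lx, nrow(C), length(w_range), byrow = TRUE)
  sx <- rowSums(X * use); sy <- rowSums(L * use)
  sxx <- rowSums(X * X * use); sxy <- rowSums(X * L * use)
  den <- n * sxx - sx^2
  slope <- ifelse(n >= 2 & den > 0, (n * sxy - sx * sy) / den, 0)
  raw <- matrix(pmin(pmax(slope, 0), 2), nrow(binary), ncol(binary))
  rng <- range(raw)
  norm <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  structure(list(data = norm, raw = raw, w_range = w_range),
            class = "lfd_map")
}

#' @export
print.lfd_map <- function(x, ...) {
  cat(sprintf("<lfd_map> %d x %d px, w in %d..%d, raw range [%.3f, %.3f]\n",
              nrow(x$data), ncol(x$data), min(x$w_range), max(x$w_range),
              min(x$raw), max(x$raw)))
  invisible(x)
}

#' Vessel map from a local-fractal-dimension map
#'
#' Thresholds the normalised LFD map.  When the binarised image that the
#' map was computed from is supplied, the vessel map is additionally
#' restricted to its white pixels, so the LFD acts as a noise filter
#' (isolated white pixels have slope 0 and are dropped) without dilating
#' the vessels by the window radius.
#'
#' @param lfd an `lfd_map`.
#' @param threshold fraction of the normalised range, in (0,1).
#' @param binary optional logical matrix to intersect with.
#' @return logical vessel matrix.
#' @export
vessel_map_from_lfd <- function(lfd, threshold = 0.25, binary = NULL) {
  stopifnot(inherits(lfd, "lfd_map"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)")
  v <- lfd$data >= threshold
  if (!is.null(binary)) v <- v & binary
  v
}

#' Extract the foveal avascular zone from a vessel map
#'
#' Morphological opening removes residual noise, the map is inverted, and
#' the largest 8-connected avascular component within the central part of
#' the field is returned (the peripheral background is avascular too and
#' would otherwise win).  The component is finally regularised by a small
#' opening which removes hairline protrusions into inter-capillary gaps.
#'
#' @param vessels logical vessel matrix.
#' @param open_radius radius of the pre-inversion opening (pixels).
#' @param central_fraction side fraction of the centred search window.
#' @param regularize_radius radius of the opening applied to the extracted
#'   mask; 0 disables.
#' @return logical FAZ mask.
#' @export
extract_faz <- function(vessels, open_radius = 1, central_fraction = 0.5,
                        regularize_radius = 2) {
  if (!any(!vessels)) stop("no avascular component: the image is all vessel")
  if (!any(vessels)) {
    warning("vessel-free image: the full field is one avascular component")
    return(matrix(TRUE, nrow(vessels), ncol(vessels)))
  }
  v <- if (open_radius > 0) {
    open_mask(vessels * 1L, disk_element(open_radius)) == 1L
  } else vessels
  av <- !v
  nr <- nrow(av); nc <- ncol(av)
  mr <- round(nr * (1 - central_fraction) / 2)
  mc <- round(nc * (1 - central_fraction) / 2)
  cen <- matrix(FALSE, nr, nc)
  cen[(mr + 1):(nr - mr), (mc + 1):(nc - mc)] <- TRUE
  lab <- label_components(av & cen)
  if (max(lab) == 0) stop("no avascular component inside the central window")
  faz <- lab == 1L
  if (regularize_radius > 0)
    faz <- open_mask(faz * 1L, disk_element(regularize_radius)) == 1L
  faz
}

#' FAZ morphology indicators
#'
#' Area (pixel count times pitch squared), perimeter (sub-pixel
#' marching-squares contour length, [contour_length()]), and the
#' isoperimetric circularity index `4 * pi * S / P^2`, clipped to at most 1
#' to absorb discretisation overshoot on near-circular shapes.
#'
#' @param faz logical FAZ mask, non-empty.
#' @param pitch_mm lateral pixel pitch in mm.
#' @return a `faz_report`: list with `area_mm2`, `perimeter_mm`,
#'   `circularity`, `centroid_px`, `mask`.
#' @export
faz_indicators <- function(faz, pitch_mm) {
  if (!any(faz)) stop("empty FAZ mask")
  area <- sum(faz) * pitch_mm^2
  per <- contour_length(faz) * pitch_mm
  ci <- min(4 * pi * area / per^2, 1)
  w <- which(faz, arr.ind = TRUE)
  structure(list(area_mm2 = area, perimeter_mm = per, circularity = ci,
                 centroid_px = c(x = mean(w[, 2]), y = mean(w[, 1])),
                 mask = faz),
            class = "faz_report")
}

#' @export
print.faz_report <- function(x, ...) {
  cat(sprintf(
    "<faz_report> area %.4f mm^2, perimeter %.4f mm, circularity %.4f\n",
    x$area_mm2, x$perimeter_mm, x$circularity))
  invisible(x)
}

#' Quadrant partition of the macular field
#'
#' Pixels within `r_excl_mm` of the centre are labelled `"excluded"`; the
#' rest are assigned by angle from the centre with boundaries on the
#' +/-45 degree diagonals.  The default `label_map` places T (temporal) on
#' the left, S (superior) on top, N (nasal) on the right and I (inferior)
#' at the bottom; swap T and N for the fellow eye.  Pixels exactly on a
#' diagonal belong to the horizontal (left/right) quadrants.
#'
#' @param shape integer vector `c(n_row, n_col)`.
#' @param center_px centre `c(x, y)` in pixel coordinates.
#' @param r_excl_mm exclusion radius in mm.
#' @param pitch_mm pixel pitch in mm.
#' @param label_map named character vector with entries `left`, `top`,
#'   `right`, `bottom`.
#' @return character matrix with values in
#'   `c(label_map, "excluded")`.
#' @export
quadrant_partition <- function(shape, center_px, r_excl_mm = 0.5,
                               pitch_mm = 1,
                               label_map = c(left = "T", top = "S",
                                             right = "N", bottom = "I")) {
  nr <- shape[1]; nc <- shape[2]
  if (center_px[1] < 1 || center_px[1] > nc ||
      center_px[2] < 1 || center_px[2] > nr)
    stop("`center_px` lies outside the image")
  if (r_excl_mm < 0) stop("`r_excl_mm` must be non-negative")
  gx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  gy <- matrix(rep(seq_len(nr), nc), nr, nc)
  dx <- gx - center_px[1]
  dy <- -(gy - center_px[2])    # image rows grow downward; dy points up
  lab <- matrix("", nr, nc)
  lab[abs(dx) >= abs(dy) & dx < 0] <- label_map[["left"]]
  lab[abs(dy) > abs(dx) & dy > 0] <- label_map[["top"]]
  lab[abs(dx) >= abs(dy) & dx >= 0] <- label_map[["right"]]
  lab[abs(dy) > abs(dx) & dy <= 0] <- label_map[["bottom"]]
  lab[(dx^2 + dy^2) * pitch_mm^2 <= r_excl_mm^2] <- "excluded"
  lab
}

#' Vessel density of a region of interest
#'
#' `100 * |vessels AND roi| / |roi|` percent.
#'
#' @param vessels logical vessel matrix.
#' @param roi logical region of interest, non-empty, same shape.
#' @return vessel density in percent.
#' @export
vessel_density <- function(vessels, roi) {
  if (!all(dim(vessels) == dim(roi))) stop("mask shapes differ")
  if (!any(roi)) stop("empty ROI: zero denominator")
  100 * sum(vessels & roi) / sum(roi)
}

#' Full clinical quantification of an en face angiogram
#'
#' Runs the automated indicator pipeline: adaptive binarisation, local
#' fractal dimension, LFD-filtered vessel map, FAZ extraction and
#' morphology, and per-quadrant vessel density around the FAZ centroid.
#'
#' @param ang an `angiogram` (or numeric matrix with `pitch_mm` given).
#' @param pitch_mm pixel pitch; taken from the angiogram when missing.
#' @param block,offset see [adaptive_binarize()].
#' @param w_range,lfd_threshold see [local_fractal_dimension()] and
#'   [vessel_map_from_lfd()].
#' @param r_excl_mm quadrant exclusion radius.
#' @param label_map quadrant labels, see [quadrant_partition()].
#' @param open_radius,central_fraction,regularize_radius see
#'   [extract_faz()].
#' @return list with `faz` (a `faz_report`), `vd` (a `vd_report`: named
#'   densities in percent and the exclusion radius), `vessel_map`, `lfd`.
#' @export
quantify_angiogram <- function(ang, pitch_mm = NULL, block = 31,
                               offset = 0.02, w_range = 2:6,
                               lfd_threshold = 0.25, r_excl_mm = 0.5,
                               label_map = c(left = "T", top = "S",
                                             right = "N", bottom = "I"),
                               open_radius = 1, central_fraction = 0.5,
                               regularize_radius = 2) {
  img <- if (inherits(ang, "angiogram")) ang$data else ang
  if (is.null(pitch_mm))
    pitch_mm <- if (inherits(ang, "angiogram")) ang$pixel_pitch_mm else
      stop("`pitch_mm` required")
  bin <- adaptive_binarize(img, block = block, offset = offset)
  lfd <- local_fractal_dimension(bin, w_range = w_range)
  vmap <- vessel_map_from_lfd(lfd, threshold = lfd_threshold, binary = bin)
  faz <- extract_faz(vmap, open_radius = open_radius,
                     central_fraction = central_fraction,
                     regularize_radius = regularize_radius)
  rep_faz <- faz_indicators(faz, pitch_mm)
  qlab <- quadrant_partition(dim(img), center_px = rep_faz$centroid_px,
                             r_excl_mm = r_excl_mm, pitch_mm = pitch_mm,
                             label_map = label_map)
  dens <- vapply(unname(label_map),
                 function(q) vessel_density(vmap, qlab == q), numeric(1))
  names(dens) <- unname(label_map)
  vd <- structure(list(densities = dens, exclusion_radius_mm = r_excl_mm),
                  class = "vd_report")
  list(faz = rep_faz, vd = vd, vessel_map = vmap, lfd = lfd)
}

#' @export
print.vd_report <- function(x, ...) {
  cat("<vd_report> vessel density (%):",
      paste(sprintf("%s=%.2f", names(x$densities), x$densities),
            collapse = ", "),
      sprintf("(excl. r=%.2f mm)\n", x$exclusion_radius_mm))
  invisible(x)
}
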