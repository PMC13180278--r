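#' Specification of a synthetic SD-OCT phantom
#'
#' Collects every knob of the spectral phantom generator and validates the
#' invariants.  The defaults describe the study conditions used throughout
#' the package's tests: a 256-sample spectrum, a 64 x 64 lateral raster with
#' four repeated B-scans per slow-axis position, a three-layer retina
#' between depth fractions 0.20 and 0.56, a perifoveal vessel ring with six
#' radial branches in the inner-retina slab and a sparse capillary grid in
#' the middle-retina slab, and fully developed blood speckle that is
#' re-drawn between repeats according to the `decorrelation` scale.
#'
#' @param n_k spectral samples per A-scan; a power of two, >= 64.
#' @param n_x A-scans per B-scan.
#' @param n_y B-scan (slow-axis) positions.
#' @param n_repeat repeated B-scans per position, >= 2.
#' @param layer_depths named, strictly increasing depth fractions in (0,1)
#'   of the layer surfaces (the first and last delimit the retina band).
#' @param layer_reflectivity mean reflectivity of each layer (one fewer
#'   than surfaces).
#' @param vessel_pattern list with `n_branch` (radial branches in the IR
#'   slab), `radius_px` (tube radius), `grid_step` (capillary grid step in
#'   the MR slab), `flow_range` (per-vessel relative flow-speed factors,
#'   sub-interval of \[0,1\]).
#' @param faz_shape list with `semi_axes_mm` (length 2) and `rotation`
#'   (radians) of the foveal avascular ellipse.
#' @param decorrelation dynamic-scatterer decorrelation scale in \[0,1\]; the
#'   complex reflectivity of an in-vessel voxel is re-mixed between repeats
#'   as `sqrt(1-d) * static + sqrt(d) * fresh`.
#' @param noise_sigma additive detector noise sd on the interferogram.
#' @param speckle_texture relative complex-texture amplitude of the static
#'   layers (0 = mirror-smooth, 1 = fully developed speckle).
#' @param vessel_reflectivity reflectivity of blood relative to the
#'   surrounding layer.
#' @param dc_level reference-arm (DC) level of the interferogram.
#' @param envelope_fwhm source-envelope FWHM as a fraction of the sampled
#'   band.
#' @param pixel_pitch_mm lateral sampling pitch.
#' @param seed integer RNG seed.
#' @return a validated `phantom_spec` object.
#' @seealso [make_spectral_phantom()]
#' @export
phantom_spec <- function(n_k = 256L, n_x = 64L, n_y = 64L, n_repeat = 4L,
                         layer_depths = c(ILM = 0.20, IPL = 0.32,
                                          OPL = 0.44, BM = 0.56),
                         layer_reflectivity = c(1.0, 0.65, 0.8),
                         vessel_pattern = list(n_branch = 6L,
                                               radius_px = 2.2,
                                               grid_step = c(18L, 20L),
                                               flow_range = c(0.65, 1)),
                         faz_shape = list(semi_axes_mm = c(0.42, 0.33),
                                          rotation = 0),
                         decorrelation = 0.8,
                         noise_sigma = 0.1,
                         speckle_texture = 0.35,
                         vessel_reflectivity = 1.3,
                         dc_level = 3,
                         envelope_fwhm = 0.4,
                         pixel_pitch_mm = 0.047,
                         seed = 1L) {
  spec <- list(n_k = as.integer(n_k), n_x = as.integer(n_x),
               n_y = as.integer(n_y), n_repeat = as.integer(n_repeat),
               layer_depths = layer_depths,
               layer_reflectivity = layer_reflectivity,
               vessel_pattern = vessel_pattern, faz_shape = faz_shape,
               decorrelation = decorrelation, noise_sigma = noise_sigma,
               speckle_texture = speckle_texture,
               vessel_reflectivity = vessel_reflectivity,
               dc_level = dc_level, envelope_fwhm = envelope_fwhm,
               pixel_pitch_mm = pixel_pitch_mm, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, msg) stop(sprintf("invalid `%s`: %s", field, msg),
                                    call. = FALSE)
  with(spec, {
    if (n_k < 64 || bitwAnd(n_k, n_k - 1L) != 0L)
      fail("n_k", "must be a power of two >= 64")
    if (n_repeat < 2) fail("n_repeat", "must be >= 2")
    if (n_x < 8) fail("n_x", "must be >= 8")
    if (length(layer_depths) < 2 || is.null(names(layer_depths)) ||
        any(diff(layer_depths) <= 0) ||
        any(layer_depths <= 0) || any(layer_depths >= 1))
      fail("layer_depths", "must be named, strictly increasing, in (0,1)")
    if (length(layer_reflectivity) != length(layer_depths) - 1)
      fail("layer_reflectivity", "needs one value per layer between surfaces")
    if (decorrelation < 0 || decorrelation > 1)
      fail("decorrelation", "must lie in [0,1]")
    if (noise_sigma < 0) fail("noise_sigma", "must be non-negative")
    if (length(faz_shape$semi_axes_mm) != 2 ||
        any(faz_shape$semi_axes_mm <= 0))
      fail("faz_shape", "semi_axes_mm must be two positive lengths")
    fr <- vessel_pattern$flow_range
    if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 0 || fr[2] > 1)
      fail("vessel_pattern", "flow_range must be an interval within [0,1]")
  })
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d raster, %d repeats, n_k=%d, decorrelation=%.2f, noise=%.3g, seed=%d\n",
    x$n_x, x$n_y, x$n_repeat, x$n_k, x$decorrelation, x$noise_sigma, x$seed))
  invisible(x)
}

seq_grid <- function(from, to, by) {
  if (to < from) return(integer(0))
  seq(from, to, by = by)
}

complex_gaussian <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
}

# en face geometry of the spectral phantom: perifoveal ring + radial
# branches (IR) and a sparse capillary grid (MR); returns per-pixel
# flow-speed factor maps (0 = static).
phantom_vessel_maps <- function(spec) {
  n_x <- spec$n_x; n_y <- spec$n_y
  vp <- spec$vessel_pattern
  rt <- vp$radius_px
  if (rt <= 0) {
    z <- matrix(0, n_y, n_x)
    cx <- (n_x + 1) / 2; cy <- (n_y + 1) / 2
    ab <- spec$faz_shape$semi_axes_mm / spec$pixel_pitch_mm
    gx <- matrix(rep(seq_len(n_x), each = n_y), n_y, n_x)
    gy <- matrix(rep(seq_len(n_y), n_x), n_y, n_x)
    faz <- ((gx - cx) / ab[1])^2 + ((gy - cy) / ab[2])^2 <= 1
    return(list(flow_IR = z, flow_MR = z, faz = faz))
  }
  ab <- spec$faz_shape$semi_axes_mm / spec$pixel_pitch_mm
  cx <- (n_x + 1) / 2; cy <- (n_y + 1) / 2
  gx <- matrix(rep(seq_len(n_x), each = n_y), n_y, n_x)
  gy <- matrix(rep(seq_len(n_y), n_x), n_y, n_x)
  rot <- spec$faz_shape$rotation
  u <- (gx - cx) * cos(rot) + (gy - cy) * sin(rot)
  v <- -(gx - cx) * sin(rot) + (gy - cy) * cos(rot)
  rr <- sqrt((u / (ab[1] + rt))^2 + (v / (ab[2] + rt))^2)
  ring <- abs(rr - 1) * mean(ab + rt) <= rt
  nb <- vp$n_branch
  ang <- (seq_len(nb) - 1) / nb * 2 * pi + 0.3
  flow_IR <- matrix(0, n_y, n_x)
  flow_IR[ring] <- 1
  fr <- vp$flow_range
  for (a in ang) {
    d <- abs(-sin(a) * (gx - cx) + cos(a) * (gy - cy))
    along <- cos(a) * (gx - cx) + sin(a) * (gy - cy)
    sel <- d <= rt & along > mean(ab) & flow_IR == 0
    flow_IR[sel] <- stats::runif(1, fr[1], fr[2])
  }
  flow_MR <- matrix(0, n_y, n_x)
  for (x0 in seq_grid(8, n_x, vp$grid_step[1])) {
    sel <- abs(col(flow_MR) - x0) <= 1
    flow_MR[sel] <- pmax(flow_MR[sel], stats::runif(1, fr[1], fr[2]))
  }
  for (y0 in seq_grid(12, n_y, vp$grid_step[2])) {
    sel <- abs(row(flow_MR) - y0) <= 1
    flow_MR[sel] <- pmax(flow_MR[sel], stats::runif(1, fr[1], fr[2]))
  }
  faz <- (u / ab[1])^2 + (v / ab[2])^2 <= 1
  flow_MR[(u / ab[1])^2 + (v / ab[2])^2 <= 1.4] <- 0
  list(flow_IR = flow_IR, flow_MR = flow_MR, faz = faz)
}

#' Generate a synthetic SD-OCT spectral volume with ground truth
#'
#' Simulates repeated-B-scan acquisition of a layered retina with embedded
#' vessel networks.  Each A-line carries one complex scatterer per depth
#' bin; the interferogram is `S(k) * (DC + fringes) + noise`, where `S(k)`
#' is a Gaussian source envelope and the fringes are synthesised by an
#' inverse FFT of the complex reflectivity profile.  Static layers carry a
#' moderate complex texture (partially developed speckle); in-vessel voxels
#' carry fully developed speckle that is re-mixed between repeats with
#' weight `decorrelation * flow_factor`, which produces genuine inter-repeat
#' amplitude decorrelation.  Identical seeds give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a `spectral_volume`: `data` array
#'   \[repeat, y, x, k\], `k_grid`, `meta`) and `truth` (a `ground_truth`:
#'   per-slab en face vessel masks, FAZ mask and analytic morphology,
#'   dynamic voxel mask \[y, x, z\], per-voxel flow factors and layer
#'   boundaries).
#' @export
#' @examples
#' ph <- make_spectral_phantom(phantom_spec(n_x = 16L, n_y = 8L, seed = 7L))
#' dim(ph$volume$data)
make_spectral_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  set.seed(spec$seed)
  n_k <- spec$n_k; n_x <- spec$n_x; n_y <- spec$n_y; n_rep <- spec$n_repeat
  n_z <- n_k %/% 2L
  nl <- n_x * n_y
  zb <- round(spec$layer_depths * n_z)
  n_layer <- length(zb) - 1L

  maps <- phantom_vessel_maps(spec)
  tube_hw <- max(1L, round(spec$vessel_pattern$radius_px))
  flow3 <- array(0, c(n_y, n_x, n_z))
  if (any(maps$flow_IR > 0)) {
    zc_IR <- round(mean(zb[1:2]))
    for (dz in -tube_hw:tube_hw)
      flow3[, , zc_IR + dz] <- pmax(flow3[, , zc_IR + dz], maps$flow_IR)
  }
  if (length(zb) >= 3 && any(maps$flow_MR > 0)) {
    zc_MR <- round(mean(zb[2:3])) + 2L
    for (dz in -tube_hw:tube_hw)
      flow3[, , zc_MR + dz] <- pmax(flow3[, , zc_MR + dz], maps$flow_MR)
  }

  amp <- matrix(0, n_z, nl)
  for (s in seq_len(n_layer))
    amp[(zb[s] + 1):zb[s + 1], ] <- spec$layer_reflectivity[s]
  flowm <- matrix(aperm(flow3, c(3, 2, 1)), n_z, nl)  # col = (y-1)*n_x + x
  dyn <- flowm > 0
  amp[dyn] <- amp[dyn] * spec$vessel_reflectivity

  tex <- (1 + spec$speckle_texture * matrix(complex_gaussian(n_z * nl), n_z, nl)) /
    sqrt(1 + spec$speckle_texture^2)
  refl0 <- amp * tex
  refl0[dyn] <- amp[dyn] * complex_gaussian(sum(dyn))

  kk <- (seq_len(n_k) - 1) / n_k
  env <- exp(-(kk - 0.5)^2 / (2 * (spec$envelope_fwhm / (2 * sqrt(2 * log(2))))^2))
  dmix <- spec$decorrelation * flowm[dyn]
  nd <- sum(dyn)
  data <- array(0, c(n_rep, n_y, n_x, n_k))
  for (r in seq_len(n_rep)) {
    refl <- refl0
    refl[dyn] <- sqrt(1 - dmix) * refl0[dyn] +
      sqrt(dmix) * amp[dyn] * complex_gaussian(nd)
    C <- matrix(0i, n_k, nl)
    C[2:(n_z + 1), ] <- refl
    fr <- Re(stats::mvfft(C, inverse = TRUE))
    S <- env * (spec$dc_level + fr) +
      spec$noise_sigma * stats::rnorm(n_k * nl)
    data[r, , , ] <- aperm(array(S, c(n_k, n_x, n_y)), c(3, 2, 1))
  }

  surfaces <- lapply(zb, function(z) matrix(as.integer(z), n_y, n_x))
  names(surfaces) <- names(spec$layer_depths)
  bounds <- layer_boundaries(surfaces, source = "phantom_truth")

  ab_mm <- spec$faz_shape$semi_axes_mm
  a <- ab_mm[1]; b <- ab_mm[2]
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  area <- pi * a * b

  volume <- structure(list(data = data, k_grid = kk, meta = spec),
                      class = "spectral_volume")
  truth <- structure(list(
    vessel_mask = list(IR = maps$flow_IR > 0, MR = maps$flow_MR > 0),
    faz_mask = maps$faz,
    faz_area_mm2 = area, faz_perimeter_mm = per,
    faz_ci = 4 * pi * area / per^2,
    dynamic_voxel_mask = flow3 > 0,
    flow_factor = flow3,
    layer_boundaries = bounds),
    class = "ground_truth")
  list(volume = volume, truth = truth)
}

#' @export
print.spectral_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_volume> %d repeats x %d y x %d x x %d k-samples\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Generate a synthetic en face angiogram with ground truth
#'
#' Draws a macula-like en face scene: an elliptical foveal avascular zone
#' sealed by a thin perifoveal capillary ring, surrounded by a jittered
#' capillary mesh whose enclosed inter-capillary pockets are much smaller
#' than the FAZ.  The grayscale image is the blurred vessel map under
#' multiplicative gamma speckle plus a weak noise floor.  The ground truth
#' records the exact vessel and FAZ masks, the analytic ellipse morphology
#' and the per-quadrant vessel fill.
#'
#' @param n_px image side in pixels.
#' @param faz_shape list with `semi_axes_mm` and `rotation` as in
#'   [phantom_spec()]; the ellipse must fit inside the image.
#' @param vessel_fill target capillary area fraction in (0,1); the mesh
#'   spacing is derived from it.
#' @param seed integer RNG seed.
#' @param pixel_pitch_mm lateral pitch (default 0.0125 mm, a 3 mm field).
#' @param speckle_shape gamma shape of the multiplicative speckle; the
#'   default 36 corresponds to the speckle contrast of a heavily averaged
#'   angiogram.
#' @param blur_sigma optical blur sd in pixels.
#' @param background background reflectance level.
#' @return list with `angiogram` (an `angiogram` object) and `truth` (a
#'   `ground_truth` with `vessel_mask`, `faz_mask`, analytic `faz_area_mm2`,
#'   `faz_perimeter_mm`, `faz_ci`, and `quadrant_density` in percent).
#' @export
#' @examples
#' ph <- make_enface_phantom(n_px = 120, seed = 3)
#' ph$truth$faz_ci
make_enface_phantom <- function(n_px = 240L,
                                faz_shape = list(semi_axes_mm = c(0.30, 0.24),
                                                 rotation = 0.4),
                                vessel_fill = 0.53, seed = 1L,
                                pixel_pitch_mm = 0.0125,
                                speckle_shape = 36, blur_sigma = 0.6,
                                background = 0.06) {
  if (vessel_fill <= 0 || vessel_fill >= 1)
    stop("`vessel_fill` must lie in (0,1)")
  ab <- faz_shape$semi_axes_mm / pixel_pitch_mm
  if (any(2 * ab >= n_px - 20))
    stop("FAZ ellipse does not fit inside the image")
  set.seed(seed)
  cx <- (n_px + 1) / 2; cy <- (n_px + 1) / 2
  gx <- matrix(rep(seq_len(n_px), each = n_px), n_px, n_px)
  gy <- matrix(rep(seq_len(n_px), n_px), n_px, n_px)
  rot <- faz_shape$rotation
  u <- (gx - cx) * cos(rot) + (gy - cy) * sin(rot)
  v <- -(gx - cx) * sin(rot) + (gy - cy) * cos(rot)
  faz <- (u / ab[1])^2 + (v / ab[2])^2 <= 1
  sr <- sqrt((u / ab[1])^2 + (v / ab[2])^2)
  hw <- 3.2 / min(ab)                     # ring radial half-thickness
  ring <- sr >= 1 & sr <= 1 + 2 * hw

  line_w <- 7                              # drawn capillary width in px
  spacing <- max(10L, round(line_w / (1 - sqrt(1 - vessel_fill))))
  ves <- ring
  for (x0 in seq(4 + floor(stats::runif(1, 0, spacing)), n_px, by = spacing)) {
    xo <- x0 + round(2 * sin(gy[, 1] / 17 + stats::runif(1, 0, 6)))
    ves <- ves | (abs(sweep(gx, 1, xo, `-`)) <= (line_w - 1) / 2)
  }
  for (y0 in seq(4 + floor(stats::runif(1, 0, spacing)), n_px, by = spacing)) {
    yo <- y0 + round(2 * sin(gx[1, ] / 15 + stats::runif(1, 0, 6)))
    ves <- ves | (abs(sweep(gy, 2, yo, `-`)) <= (line_w - 1) / 2)
  }
  ves[sr < 1] <- FALSE
  ves <- ves | ring

  clean <- background + (1 - background) * gauss_smooth(ves * 1, blur_sigma)
  img <- clean * matrix(stats::rgamma(n_px^2, speckle_shape, speckle_shape),
                        n_px, n_px) +
    0.01 * matrix(abs(stats::rnorm(n_px^2)), n_px, n_px)

  a <- faz_shape$semi_axes_mm[1]; b <- faz_shape$semi_axes_mm[2]
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  area <- pi * a * b

  qlab <- quadrant_partition(dim(img), center_px = c(cx, cy),
                             r_excl_mm = 0.5, pitch_mm = pixel_pitch_mm)
  qd <- vapply(c("T", "S", "N", "I"),
               function(q) vessel_density(ves, qlab == q), numeric(1))

  ang <- new_angiogram(img, pixel_pitch_mm, slab = "enface_phantom",
                       method = "phantom")
  truth <- structure(list(
    vessel_mask = ves, faz_mask = faz,
    faz_area_mm2 = area, faz_perimeter_mm = per,
    faz_ci = 4 * pi * area / per^2,
    quadrant_density = qd),
    class = "ground_truth")
  list(angiogram = ang, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>")
  if (!is.null(x$faz_area_mm2))
    cat(sprintf(" FAZ area %.4f mm^2, perimeter %.4f mm, CI %.4f",
                x$faz_area_mm2, x$faz_perimeter_mm, x$faz_ci))
  cat("\n")
  invisible(x)
}
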