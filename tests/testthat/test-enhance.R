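test_that("structural averaging is the mean across repeats", {
  one <- array(stats::runif(2 * 3 * 4), c(1, 2, 3, 4))
  expect_equal(average_structural(one), one[1, , , ])
  two <- array(0, c(2, 1, 1, 1)); two[1, , , ] <- 1; two[2, , , ] <- 3
  expect_equal(c(average_structural(two)), 2)
  set.seed(8)
  big <- array(stats::rnorm(4 * 50 * 50 * 40), c(4, 50, 50, 40))
  v <- stats::var(c(average_structural(big)))
  expect_equal(v, 1 / 4, tolerance = 0.1)
})

test_that("layer boundaries validate anatomical ordering", {
  s1 <- matrix(10L, 4, 4); s2 <- matrix(20L, 4, 4)
  b <- layer_boundaries(list(A = s1, B = s2), source = "external")
  expect_s3_class(b, "layer_boundaries")
  s2bad <- s2; s2bad[1, 1] <- 5L
  expect_error(layer_boundaries(list(A = s1, B = s2bad)), "below")
})

test_that("gradient fallback recovers flat phantom surfaces within one bin", {
  spec <- phantom_spec(n_x = 32L, n_y = 16L, seed = 3L, noise_sigma = 0,
                       layer_reflectivity = c(1, 0.4, 0.95),
                       vessel_pattern = list(n_branch = 0L, radius_px = 0,
                                             grid_step = c(18L, 20L),
                                             flow_range = c(0.65, 1)))
  ph <- make_spectral_phantom(spec)
  pre <- preprocess_spectra(ph$volume)
  st <- average_structural(amplitude_volume(reconstruct_complex(pre,
                                                                rep(1, 256))))
  b <- segment_layers_fallback(st, 4, names(spec$layer_depths),
                               lateral_halfwidth = 16L)
  tr <- ph$truth$layer_boundaries
  hits <- 0; tot <- 0
  for (s in names(tr$surfaces)) {
    d <- abs(b$surfaces[[s]] - tr$surfaces[[s]])
    hits <- hits + sum(d <= 1); tot <- tot + length(d)
  }
  expect_gte(hits / tot, 0.99)
  expect_identical(b$source, "gradient_fallback")
  # a uniform volume has no gradient maxima
  expect_error(segment_layers_fallback(array(1, c(4, 8, 64)), 4),
               "maxima")
})

test_that("B-scan Otsu truncation obeys the masking contract and a
           brute-force threshold oracle", {
  img <- matrix(0, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[, 1:3] <- TRUE
  img[, 1] <- 1; img[, 2] <- c(1, 1, 1, 9, 9, 9); img[, 3] <- 9
  img[, 4:6] <- 100
  out <- enhance_flow_bscan(img, mask, clip_quantile = 1)
  expect_true(all(out[, 4:6] == 0))          # out-of-mask forced to zero
  # brute-force Otsu over all 256 candidate thresholds on the in-mask values
  v <- img[mask]
  cand <- min(v) + (1:256) / 256 * (max(v) - min(v))
  bcv <- vapply(cand, function(t0) {
    lo <- v[v < t0]; hi <- v[v >= t0]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
  }, numeric(1))
  thr <- cand[which.max(bcv)]
  expect_equal(out[mask], ifelse(v < thr, 0, v))
  expect_true(all(out[img == 1 & mask] == 0))  # low mode removed
  expect_true(all(out[img == 9 & mask] == 9))  # high mode kept
  # degenerate: constant in-mask values survive unchanged
  flat <- matrix(5, 4, 4); m <- matrix(TRUE, 4, 4)
  expect_equal(enhance_flow_bscan(flat, m), flat)
  expect_error(enhance_flow_bscan(flat, matrix(FALSE, 4, 4)), "empty")
  expect_error(enhance_flow_bscan(flat, matrix(TRUE, 2, 2)), "shape")
})

test_that("enhancement is idempotent once the floor is removed", {
  set.seed(5)
  img <- matrix(c(stats::runif(50, 0, 0.1), stats::runif(50, 5, 6)), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  e1 <- enhance_flow_bscan(img, mask, clip_quantile = 1)
  e2 <- enhance_flow_bscan(e1, mask, clip_quantile = 1)
  # the in-mask minimum of e1 (0) and its maximum define a histogram whose
  # Otsu threshold separates zeros from signal, which e1 already satisfies
  expect_equal(e2[e1 > 0], e1[e1 > 0])
})

test_that("en face projection: constants, single planes, and linearity", {
  f <- new_flow <- array(0, c(4, 6, 20))
  f[] <- 3
  fv <- octawalsh:::new_flow_volume(f, "test", 4L)
  s1 <- matrix(5L, 4, 6); s2 <- matrix(12L, 4, 6)
  b <- layer_boundaries(list(top = s1, bot = s2), source = "external")
  sl <- slab_spec("S", "top", "bot")
  p <- enface_project(fv, b, sl)
  expect_equal(p$data, matrix(3, 4, 6))
  # thickness-one slab copies that plane
  b1 <- layer_boundaries(list(top = s1, bot = s1 + 1L), source = "external")
  set.seed(2); f2 <- array(stats::rnorm(4 * 6 * 20), c(4, 6, 20))
  fv2 <- octawalsh:::new_flow_volume(f2, "test", 4L)
  expect_equal(enface_project(fv2, b1, sl)$data, f2[, , 6])
  # linearity
  fv3 <- octawalsh:::new_flow_volume(2 * f2 + 5 * f, "test", 4L)
  expect_equal(enface_project(fv3, b, sl)$data,
               2 * enface_project(fv2, b, sl)$data +
                 5 * enface_project(fv, b, sl)$data,
               tolerance = 1e-12)
  # empty slab positions project to zero with a warning
  s_eq <- s1; bz <- layer_boundaries(list(top = s1, bot = s2),
                                     source = "external")
  bz$surfaces$bot[1, 1] <- bz$surfaces$top[1, 1]
  expect_warning(pz <- enface_project(fv2, bz, sl), "empty")
  expect_equal(pz$data[1, 1], 0)
})

test_that("projected vessels overlap the ground-truth en face network", {
  ph <- default_phantom()
  fl <- default_flow_ours()
  sl <- slab_spec("IR", "ILM", "IPL")
  ang <- enface_project(fl, ph$truth$layer_boundaries, sl)
  m <- ang$data >= otsu_threshold(c(ang$data))
  gt <- ph$truth$vessel_mask$IR
  dice <- 2 * sum(m & gt) / (sum(m) + sum(gt))
  expect_gte(dice, 0.8)
})

test_that("volume-scope and bscan-scope enhancement share the masking
           contract", {
  ph <- default_phantom()
  fl <- default_flow_ours()
  bounds <- ph$truth$layer_boundaries
  for (scope in c("volume", "bscan")) {
    enh <- enhance_flow_volume(fl, bounds, scope = scope)
    d <- dim(enh$data)
    zb <- vapply(bounds$surfaces, function(s) s[1, 1], integer(1))
    outside <- enh$data[, , c(seq_len(zb[1]), (zb[length(zb)] + 1):d[3])]
    expect_equal(max(abs(outside)), 0)
    kept <- enh$data > 0
    expect_equal(fl$data[kept], enh$data[kept])
  }
})
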