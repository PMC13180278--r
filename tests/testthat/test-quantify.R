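test_that("adaptive binarisation: constants, shift invariance, line recovery", {
  flat <- matrix(2, 40, 40)
  expect_false(any(adaptive_binarize(flat, block = 11, offset = 0.01)))
  set.seed(4)
  img <- matrix(stats::runif(40 * 40), 40, 40)
  b1 <- adaptive_binarize(img, block = 11, offset = 0.05)
  b2 <- adaptive_binarize(img + 17.3, block = 11, offset = 0.05)
  expect_identical(b1, b2)
  line <- matrix(0, 41, 41); line[21, ] <- 1
  br <- adaptive_binarize(line, block = 11, offset = 0.1)
  expect_identical(br, line == 1)
  expect_error(adaptive_binarize(img, block = 10), "odd")
})

test_that("local fractal dimension attains its limiting values", {
  white <- matrix(TRUE, 31, 31)
  lw <- local_fractal_dimension(white)
  expect_equal(lw$raw[16, 16], 2)
  expect_true(all(abs(lw$raw[10:22, 10:22] - 2) < 1e-12))
  line <- matrix(FALSE, 31, 31); line[16, ] <- TRUE
  ll <- local_fractal_dimension(line)
  expect_equal(ll$raw[16, 16], 1, tolerance = 1e-12)
  black <- matrix(FALSE, 31, 31)
  lb <- local_fractal_dimension(black)
  expect_equal(max(lb$raw), 0)
  expect_equal(max(lb$data), 0)
})

test_that("raw LFD values stay in [0,2] and match a brute-force count
           regression at sample pixels", {
  set.seed(9)
  bin <- matrix(stats::runif(60 * 60) < 0.3, 60, 60)
  lfd <- local_fractal_dimension(bin)
  expect_true(all(lfd$raw >= 0 & lfd$raw <= 2))
  expect_true(all(lfd$data >= 0 & lfd$data <= 1))
  # brute-force single-pixel oracle (interior pixels, no padding effects)
  for (p in list(c(20, 20), c(35, 42))) {
    counts <- vapply(2:6, function(w)
      sum(bin[(p[1] - w):(p[1] + w), (p[2] - w):(p[2] + w)]), numeric(1))
    use <- counts > 0
    fit <- stats::lm(log(counts[use]) ~ log(2 * (2:6)[use] + 1))
    expect_equal(lfd$raw[p[1], p[2]],
                 min(max(unname(stats::coef(fit)[2]), 0), 2),
                 tolerance = 1e-9)
  }
})

test_that("LFD vessel maps: bare thresholding dilates, the binary-restricted
           map does not, and isolated noise pixels are dropped", {
  line <- matrix(FALSE, 41, 41); line[21, ] <- TRUE
  line[5, 5] <- TRUE                     # isolated noise pixel
  lfd <- local_fractal_dimension(line)
  bare <- vessel_map_from_lfd(lfd, threshold = 1e-6)
  # pixels up to 5 rows away still see the line at two or more scales
  expect_true(all(bare[16:26, 15:27]))
  restricted <- vessel_map_from_lfd(lfd, threshold = 0.25, binary = line)
  expect_true(all(restricted[21, 2:40]))
  expect_false(restricted[5, 5])         # slope 0 at the isolated pixel
  expect_false(any(restricted & !line))
})

test_that("FAZ extraction recovers an annulus interior", {
  n <- 141; r_in <- 30; r_out <- 45
  d2 <- (row(matrix(0, n, n)) - 71)^2 + (col(matrix(0, n, n)) - 71)^2
  ves <- d2 >= r_in^2 & d2 <= r_out^2
  faz <- extract_faz(ves)
  expect_lte(abs(sum(faz) - pi * r_in^2) / (pi * r_in^2), 0.05)
  expect_error(extract_faz(matrix(TRUE, 10, 10)), "all vessel")
  expect_warning(f0 <- extract_faz(matrix(FALSE, 10, 10)), "vessel-free")
  expect_true(all(f0))
})

test_that("FAZ indicators: disc, square and exact-area fixtures", {
  n <- 121
  d2 <- (row(matrix(0, n, n)) - 61)^2 + (col(matrix(0, n, n)) - 61)^2
  disc <- d2 <= 40^2
  rep_d <- faz_indicators(disc, pitch_mm = 0.01)
  expect_gte(rep_d$circularity, 0.95)
  expect_lte(rep_d$circularity, 1)
  sq <- matrix(FALSE, n, n); sq[31:90, 31:90] <- TRUE
  rep_s <- faz_indicators(sq, pitch_mm = 0.01)
  expect_equal(rep_s$circularity, pi / 4, tolerance = 0.05)
  all_mask <- matrix(TRUE, 100, 100)
  expect_equal(faz_indicators(all_mask, 0.01)$area_mm2, 1.0)
  expect_error(faz_indicators(matrix(FALSE, 5, 5), 0.01), "empty")
})

test_that("quadrant partition geometry and tie rule", {
  lab <- quadrant_partition(c(101, 101), center_px = c(51, 51),
                            r_excl_mm = 10, pitch_mm = 1)
  expect_identical(lab[51, 91], "N")   # pure +x
  expect_identical(lab[51, 11], "T")   # pure -x
  expect_identical(lab[11, 51], "S")   # up
  expect_identical(lab[91, 51], "I")
  expect_identical(lab[51, 52], "excluded")
  counts <- table(factor(lab, levels = c("T", "S", "N", "I")))
  expect_identical(counts[["T"]], counts[["N"]])
  expect_identical(counts[["S"]], counts[["I"]])
  # diagonals belong to the horizontal quadrants
  expect_identical(lab[21, 81], "N")   # dx = 30, dy = 30 tie
  gx <- matrix(rep(1:101, each = 101), 101, 101) - 51
  gy <- 51 - matrix(rep(1:101, 101), 101, 101)
  n_diag_left <- sum(abs(gx) == abs(gy) & gx < 0 & gx^2 + gy^2 > 100)
  expect_identical(counts[["T"]] - counts[["S"]], as.integer(n_diag_left))
  expect_error(quadrant_partition(c(10, 10), center_px = c(50, 5)), "outside")
})

test_that("vessel density is an exact pixel ratio and rotation-invariant", {
  roi <- matrix(TRUE, 10, 10)
  ves <- matrix(FALSE, 10, 10); ves[, 1:5] <- TRUE
  expect_equal(vessel_density(ves, roi), 50)
  expect_equal(vessel_density(roi, roi), 100)
  set.seed(12)
  v <- matrix(stats::runif(400) < 0.4, 20, 20)
  r <- matrix(stats::runif(400) < 0.6, 20, 20)
  r[1, 1] <- TRUE
  expect_equal(vessel_density(v, r), 100 * sum(v & r) / sum(r))
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(vessel_density(rot(v), rot(r)), vessel_density(v, r))
  expect_error(vessel_density(v, r & FALSE), "empty")
})

test_that("the full quantification chain recovers en face phantom truth", {
  ph <- make_enface_phantom(n_px = 240L, seed = 31L)
  q <- quantify_angiogram(ph$angiogram)
  expect_gte(dice_and_errors(q$faz$mask, ph$truth$faz_mask)$dice, 0.95)
  expect_lte(abs(q$faz$area_mm2 - ph$truth$faz_area_mm2) /
               ph$truth$faz_area_mm2, 0.05)
  expect_lte(abs(q$faz$circularity - ph$truth$faz_ci), 0.05)
  d <- dice_and_errors(q$vessel_map, ph$truth$vessel_mask)
  expect_gte(d$dice, 0.85)
})

test_that("LFD separates vessel calibres on a sparse scene: blobs above
           capillary lines above empty background", {
  img <- matrix(FALSE, 80, 80)
  img[20:28, 10:70] <- TRUE          # large vessel
  img[60, 10:70] <- TRUE             # capillary
  lfd <- local_fractal_dimension(img)
  big <- mean(lfd$data[24, 20:60])
  thin <- mean(lfd$data[60, 20:60])
  bg <- mean(lfd$data[45:50, 20:60])
  expect_gt(big, thin)
  expect_gt(thin, bg)
})
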