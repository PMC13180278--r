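test_that("fused mask: mean of identical images equals the single-image
           mask, thick bars thin to one-pixel lines", {
  set.seed(3)
  img <- matrix(stats::runif(40 * 40), 40, 40)
  img[15:25, 5:35] <- img[15:25, 5:35] + 2
  m1 <- fused_vessel_mask(list(img))
  m3 <- fused_vessel_mask(list(img, img, img))
  expect_identical(m1, m3)
  bar <- matrix(0, 21, 40); bar[8:13, 3:38] <- 1
  sk <- fused_vessel_mask(list(bar))
  expect_true(all(colSums(sk[, 7:34]) == 1))    # one pixel per column
  expect_warning(mb <- fused_vessel_mask(list(matrix(0, 5, 5))), "blank")
  expect_equal(sum(mb), 0)
  expect_error(fused_vessel_mask(list(img, matrix(0, 2, 2))), "shapes")
})

test_that("skeleton pixels have at most two neighbours away from junctions", {
  bar <- matrix(0, 21, 40); bar[8:13, 3:38] <- 1
  sk <- thin_skeleton(bar)
  nb <- octawalsh:::apply_kernel(sk, matrix(1L, 3, 3), `+`, 0L) - sk
  expect_true(all(nb[sk == 1] <= 2))
})

test_that("background mask is the complement of the cross dilation", {
  expect_equal(background_mask(matrix(0L, 4, 4)), matrix(1L, 4, 4))
  M <- matrix(0L, 5, 5); M[3, 3] <- 1L
  N <- background_mask(M)
  expect_equal(sum(N), 20)
  expect_false(any(M == 1 & N == 1))
  Nsq <- background_mask(M, element = "square")
  expect_equal(sum(Nsq), 16)
})

test_that("quality metrics reproduce closed-form toys", {
  img <- matrix(0, 6, 6)
  M <- matrix(0L, 6, 6); M[3, 2:3] <- 1L
  img[3, 2] <- 2; img[3, 3] <- 4
  N <- background_mask(M)
  img[N == 1] <- rep(c(0, 2), length.out = sum(N))  # population sd 1

  q <- quality_metrics(img, M, N)
  expect_equal(q$connectivity, 1)        # population sd of {2,4}
  expect_equal(q$contrast, 3)            # mean 3 / sd 1
  # snr toy: in-mask mean 10 over background sd 1
  img2 <- img; img2[3, 2] <- 8; img2[3, 3] <- 12   # mean 10
  q2 <- quality_metrics(img2, M, N)
  expect_equal(q2$snr_db, 10 * log10(10 / 1))
  # zero in-mask deviation names the metric in the error
  img3 <- img; img3[3, 2:3] <- 5
  expect_error(quality_metrics(img3, M, N), "contrast")
})

test_that("quality metrics match brute-force loops on random images", {
  set.seed(6)
  img <- matrix(stats::runif(64), 8, 8)
  M <- matrix(0L, 8, 8); M[cbind(c(2, 3, 4, 6), c(2, 5, 7, 3))] <- 1L
  N <- background_mask(M)
  q <- quality_metrics(img, M, N)
  vm <- c(); vn <- c()
  for (i in 1:8) for (j in 1:8) {
    if (M[i, j] == 1) vm <- c(vm, img[i, j])
    if (N[i, j] == 1) vn <- c(vn, img[i, j])
  }
  psd <- function(v) sqrt(sum((v - sum(v) / length(v))^2) / length(v))
  expect_equal(q$connectivity, psd(vm), tolerance = 1e-10)
  expect_equal(q$contrast, mean(vm) / psd(vm), tolerance = 1e-10)
  expect_equal(q$snr_db, 10 * log10(mean(vm) / psd(vn)), tolerance = 1e-10)
})

test_that("LCC ratio counts skeleton pixels in the largest component", {
  img <- matrix(0, 60, 60)
  img[10, 5:44] <- 1                      # long curve
  img[40, 10:19] <- 1                     # short curve
  r <- lcc_ratio(img, block = 15, offset = 0.05)
  sk <- thin_skeleton(adaptive_binarize(img, block = 15, offset = 0.05))
  sizes <- sort(flood_components(sk == 1), decreasing = TRUE)
  expect_equal(r, 100 * sizes[1] / sum(sizes), tolerance = 1e-12)
  # one isolated dot strictly lowers the ratio
  img2 <- img; img2[55, 55] <- 1
  expect_lt(lcc_ratio(img2, block = 15, offset = 0.05), r)
  # a single connected curve scores 100
  img3 <- matrix(0, 30, 30); img3[15, 3:27] <- 1
  expect_equal(lcc_ratio(img3, block = 15, offset = 0.05), 100)
  expect_error(lcc_ratio(matrix(0, 20, 20)), "skeleton")
})

test_that("Dice and error rates: toys, symmetry and asymmetry", {
  gt <- matrix(FALSE, 20, 20); gt[1:10, 1:10] <- TRUE      # 100 px
  seg <- matrix(FALSE, 20, 20); seg[1:10, 2:11] <- TRUE    # 100 px, 90 common
  r <- dice_and_errors(seg, gt)
  expect_equal(r$dice, 0.9)
  expect_equal(r$fp_rate_pct, 10)
  expect_equal(r$fn_rate_pct, 10)
  expect_equal(dice_and_errors(gt, gt)$dice, 1)
  expect_equal(dice_and_errors(gt, gt)$fp_rate_pct, 0)
  disj <- matrix(FALSE, 20, 20); disj[15:18, 15:18] <- TRUE
  expect_equal(dice_and_errors(disj, gt)$dice, 0)
  # dice is symmetric, the error rates are not
  gt2 <- matrix(FALSE, 20, 20); gt2[1:5, 1:10] <- TRUE
  expect_equal(dice_and_errors(seg, gt2)$dice, dice_and_errors(gt2, seg)$dice)
  expect_false(isTRUE(all.equal(dice_and_errors(seg, gt2)$fp_rate_pct,
                                dice_and_errors(gt2, seg)$fp_rate_pct)))
  expect_error(dice_and_errors(seg, gt & FALSE), "empty")
})

test_that("ICC(A,1) matches an ANOVA-based oracle and penalises offsets", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  icc <- icc_agreement(x, y)
  # independent oracle: two-way ANOVA mean squares via aov()
  d <- data.frame(score = c(x, y),
                  subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(score ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 / 6 * (ms[2] - ms[3]))
  expect_equal(icc, oracle, tolerance = 1e-10)
  z <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(z, z), 1)
  expect_lt(icc_agreement(z, z + 100), 0.1)
  expect_error(icc_agreement(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(icc_agreement(rep(1, 4), rep(1, 4)), "variance")
})

test_that("paired effect statistics match textbook formulas", {
  a <- c(5.1, 6.2, 5.8, 7.0, 6.5)
  b <- c(4.8, 5.9, 6.1, 6.2, 6.0)
  r <- paired_effect_stats(a, b)
  d <- a - b
  t_stat <- mean(d) / (stats::sd(d) / sqrt(5))
  p_oracle <- 2 * stats::pt(-abs(t_stat), df = 4)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(r$cohen_d,
               (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2),
               tolerance = 1e-12)
  rz <- paired_effect_stats(a, b, d_type = "paired")
  expect_equal(rz$cohen_d, mean(d) / stats::sd(d), tolerance = 1e-12)
  # equal means give d = 0
  expect_equal(paired_effect_stats(c(1, 2, 3), c(3, 2, 1))$cohen_d, 0)
  # constant shift: zero-variance differences are rejected
  expect_error(paired_effect_stats(a, a + 1), "differences")
})

test_that("in-house Otsu maximises the between-class variance criterion", {
  set.seed(14)
  v <- c(stats::rnorm(400, 0.2, 0.05), stats::rnorm(100, 0.8, 0.05))
  v <- pmin(pmax(v, 0), 1)
  cand <- seq(min(v), max(v), length.out = 2000)
  bcv <- vapply(cand, function(t0) {
    lo <- v[v < t0]; hi <- v[v >= t0]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
  }, numeric(1))
  oracle <- cand[which.max(bcv)]
  expect_equal(otsu_threshold(v), oracle,
               tolerance = (max(v) - min(v)) / 100)
})
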