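#' Fused vessel skeleton from one or more angiograms
#'
#' Equal-weight pixelwise mean of the images, Otsu binarisation, and
#' Zhang-Suen thinning to a 1-pixel skeleton.  Supply display-normalised
#' images so the equal weighting is meaningful.
#'
#' @param angiograms list of `angiogram`s or numeric matrices, same shape.
#' @return integer 0/1 skeleton matrix `M`.
#' @export
fused_vessel_mask <- function(angiograms) {
  if (!is.list(angiograms)) angiograms <- list(angiograms)
  imgs <- lapply(angiograms, function(a) if (inherits(a, "angiogram")) a$data else a)
  dims <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("angiogram shapes differ")
  fused <- Reduce(`+`, imgs) / length(imgs)
  if (max(fused) <= min(fused)) {
    warning("blank fused image: empty mask")
    return(matrix(0L, nrow(fused), ncol(fused)))
  }
  thr <- otsu_threshold(c(fused))
  thin_skeleton(fused >= thr)
}

#' Background mask by dilate-and-invert
#'
#' `N = !dilate(M, element)`, with a 3x3 structuring element: the cross
#' (disk of radius 1, default) or the full square.
#'
#' @param M binary vessel mask.
#' @param element `"cross"` or `"square"`.
#' @return integer 0/1 background mask `N`, disjoint from `M`.
#' @export
background_mask <- function(M, element = c("cross", "square")) {
  element <- match.arg(element)
  k <- if (element == "cross") disk_element(1) else matrix(1L, 3, 3)
  1L - dilate_mask((M > 0) * 1L, k)
}

#' Vessel connectivity, contrast and SNR of an OCTA image
#'
#' With `I` the image, `M` the fused vessel skeleton and `N` the
#' background mask: connectivity is `Std(I | M = 1)` (lower is better),
#' contrast is `Mean(I | M = 1) / Std(I | M = 1)`, and SNR is
#' `10 log10(Mean(I | M = 1) / Std(I | N = 1))` in dB.  Standard deviations
#' are population (n-denominator) ones.
#'
#' @param img `angiogram` or numeric matrix.
#' @param M vessel skeleton (binary, non-empty).
#' @param N background mask; defaults to [background_mask()] of `M`.
#' @return a `quality_report`: list with `connectivity`, `contrast`,
#'   `snr_db`.
#' @export
quality_metrics <- function(img, M, N = background_mask(M)) {
  if (inherits(img, "angiogram")) img <- img$data
  if (!any(M > 0)) stop("vessel mask is empty")
  if (!any(N > 0)) stop("background mask is empty")
  vm <- img[M > 0]
  vn <- img[N > 0]
  s_v <- pop_sd(vm)
  s_n <- pop_sd(vn)
  if (s_v == 0) stop("contrast undefined: zero in-mask standard deviation")
  if (s_n == 0) stop("snr undefined: zero background standard deviation")
  structure(list(connectivity = s_v, contrast = mean(vm) / s_v,
                 snr_db = 10 * log10(mean(vm) / s_n)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> connectivity %.4f, contrast %.4f, SNR %.2f dB\n",
    x$connectivity, x$contrast, x$snr_db))
  invisible(x)
}

#' Largest-connected-component ratio of a vascular network
#'
#' The image is binarised by adaptive local thresholding, thinned to a
#' skeleton, and the percentage of skeleton pixels in the largest
#' 8-connected component is returned — a purely morphological continuity
#' measure.
#'
#' @param img `angiogram` or numeric matrix.
#' @param block,offset see [adaptive_binarize()].
#' @return percentage in (0, 100].
#' @export
lcc_ratio <- function(img, block = 31, offset = 0.02) {
  if (inherits(img, "angiogram")) img <- img$data
  sk <- thin_skeleton(adaptive_binarize(img, block = block, offset = offset))
  if (!any(sk > 0)) stop("empty skeleton: no vascular network found")
  lab <- label_components(sk > 0)
  100 * sum(lab == 1L) / sum(lab > 0L)
}

#' Dice similarity and false positive/negative rates
#'
#' Dice `2|A and B| / (|A| + |B|)`; the false positive rate is the
#' non-reference area wrongly segmented and the false negative rate the
#' reference area missed, both relative to the reference area, in percent.
#'
#' @param seg logical segmentation mask.
#' @param gt logical reference mask, non-empty, same shape.
#' @return a `seg_eval_report`: list with `dice`, `fp_rate_pct`,
#'   `fn_rate_pct`.
#' @export
dice_and_errors <- function(seg, gt) {
  if (!all(dim(seg) == dim(gt))) stop("mask shapes differ")
  if (!any(gt)) stop("empty reference mask: zero denominator")
  inter <- sum(seg & gt)
  structure(list(
    dice = 2 * inter / (sum(seg) + sum(gt)),
    fp_rate_pct = 100 * (sum(seg) - inter) / sum(gt),
    fn_rate_pct = 100 * (sum(gt) - inter) / sum(gt)),
    class = "seg_eval_report")
}

#' @export
print.seg_eval_report <- function(x, ...) {
  cat(sprintf("<seg_eval_report> Dice %.4f, FP %.2f%%, FN %.2f%%\n",
              x$dice, x$fp_rate_pct, x$fn_rate_pct))
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' two paired measurement series, from the classical two-way ANOVA mean
#' squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return the ICC value.
#' @export
#' @examples
#' icc_agreement(1:5, c(1.1, 2, 2.9, 4.2, 5))
icc_agreement <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need two equal-length series, n >= 3")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  if (sum((dat - grand)^2) == 0) stop("zero total variance: ICC undefined")
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Paired t-test and Cohen's d effect size
#'
#' Two-sided paired t-test p-value plus Cohen's d.  The default d scales
#' the mean difference by the pooled standard deviation of the two series,
#' `sqrt((var(a) + var(b)) / 2)`; `d_type = "paired"` gives the
#' change-score form `mean(a - b) / sd(a - b)`.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param d_type `"pooled"` or `"paired"`.
#' @return list with `p_value` and `cohen_d`.
#' @export
paired_effect_stats <- function(a, b, d_type = c("pooled", "paired")) {
  d_type <- match.arg(d_type)
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length samples, n >= 2")
  dif <- a - b
  if (all(dif == 0) || stats::sd(dif) == 0)
    stop("all pairwise differences equal: paired t-test undefined")
  p <- stats::t.test(a, b, paired = TRUE)$p.value
  d <- if (d_type == "pooled") {
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (sp == 0) stop("zero pooled standard deviation: d undefined")
    (mean(a) - mean(b)) / sp
  } else {
    mean(dif) / stats::sd(dif)
  }
  list(p_value = p, cohen_d = d)
}
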