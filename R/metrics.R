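#' Voxel confusion counts at a threshold
#'
#' Classifies every voxel of the generated volume as positive/negative by
#' strict comparison with a threshold `t`, against the ground-truth
#' classification, and reports cell counts as fractions of the total voxel
#' count. The `"standard"` convention is
#' `tp: v>t & vhat>t`, `fp: v<=t & vhat>t`, `fn: v>t & vhat<=t`,
#' `tn: v<=t & vhat<=t` (fractions partition to 1). The `"as_printed"`
#' convention reproduces the source formulas of this protocol literally:
#' its FN cell counts `v<=t & vhat<=t` -- the TN cell -- so derived
#' overlap metrics are undefined and [overlap_metrics()] refuses such
#' counts.
#'
#' @param v ground-truth volume.
#' @param vhat generated volume, same shape.
#' @param t threshold in `[0, 1]`.
#' @param convention `"standard"` or `"as_printed"`.
#' @return a `voxgan_confusion` list with `tp`, `fp`, `fn`, `tn`,
#'   `threshold`, `convention`.
#' @export
confusion_counts <- function(v, vhat, t,
                             convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  check_same_shape(v, vhat)
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  a <- unclass(v) > t
  b <- unclass(vhat) > t
  n <- length(a)
  tp <- sum(a & b) / n
  fp <- sum(!a & b) / n
  tn_std <- sum(!a & !b) / n
  fn_std <- sum(a & !b) / n
  if (convention == "standard") {
    fn <- fn_std; tn <- tn_std
  } else {
    fn <- tn_std          # literal printed formula: I(v<=t) I(vhat<=t)
    tn <- fn_std          # remaining cell, so fractions still sum to 1
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, threshold = t,
                 convention = convention),
            class = "voxgan_confusion")
}

#' Overlap metrics from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2pr/(p+r)`, `dice = 2tp/(2tp+fp+fn)`, `iou = tp/(tp+fp+fn)`.
#' Any 0/0 ratio is defined as 1 when `fp = fn = 0` (nothing to detect,
#' nothing detected) and 0 otherwise.
#'
#' @param counts a `voxgan_confusion` in the standard convention.
#' @return named list `(iou, dice, f1, precision, recall)`.
#' @export
overlap_metrics <- function(counts) {
  if (!inherits(counts, "voxgan_confusion"))
    stop("counts must come from confusion_counts()", call. = FALSE)
  if (counts$convention != "standard")
    stop("overlap metrics are undefined for as_printed counts ",
         "(their FN cell is the TN cell)", call. = FALSE)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  agree <- fp == 0 && fn == 0
  rat <- function(num, den) {
    if (den > 0) num / den else if (agree) 1 else 0
  }
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (agree) 1 else 0
  list(iou = rat(tp, tp + fp + fn),
       dice = rat(2 * tp, 2 * tp + fp + fn),
       f1 = f1, precision = precision, recall = recall)
}

#' Quantile-derived binarization threshold
#'
#' The q-quantile (linear interpolation between order statistics) of all
#' voxel values. The evaluation protocol takes Q3 (q = 0.75) to emphasize
#' rigid skeletal structure and Q1 (q = 0.25) for soft tissue, always from
#' the ground-truth volume's distribution.
#'
#' @param v a volume.
#' @param q quantile in (0, 1).
#' @return scalar threshold; monotone non-decreasing in `q`.
#' @export
quantile_threshold <- function(v, q) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("q must be a single value in (0, 1)", call. = FALSE)
  stats::quantile(as.vector(unclass(v)), q, names = FALSE, type = 7)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(1 / MSE)` with peak value 1 (volumes are normalized).
#' Identical volumes have zero error and report `Inf`.
#'
#' @param v,vhat volumes of identical shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(v, vhat) {
  check_same_shape(v, vhat)
  mse <- mean((unclass(v) - unclass(vhat))^2)
  if (mse == 0) Inf else 10 * log10(1 / mse)
}

#' Slice-averaged image-quality indices
#'
#' Each index is computed per axial slice and averaged over all slices:
#' `uqi()` is the Wang-Bovik universal quality index (sliding uniform
#' window, default 8, the covariance-luminance-contrast product -- SSIM
#' with both stability constants zero); `vsi()` is a visual
#' saliency-induced index on grayscale slices, weighting a saliency
#' similarity (band-pass frequency prior with a center prior) by a
#' Scharr-gradient similarity; `ssim_volume()` is the mean slice SSIM of
#' [ssim_2d()]. All equal 1 for identical volumes.
#'
#' @param v,vhat volumes of identical shape.
#' @param window UQI sliding window size.
#' @param cfg loss/SSIM configuration for `ssim_volume`.
#' @return scalar index.
#' @export
uqi <- function(v, vhat, window = 8L) {
  check_same_shape(v, vhat)
  mean(vapply(seq_len(dim(v)[3]), function(k)
    uqi_2d(extract_slice(v, k), extract_slice(vhat, k), window),
    numeric(1)))
}

uqi_2d <- function(a, b, window = 8L) {
  B <- min(window, dim(a))
  g <- rep(1, B)
  f <- function(x) sep_filter2_valid(x, g)
  n <- B * B
  mu1 <- f(a) / n; mu2 <- f(b) / n
  s11 <- f(a * a) / n - mu1^2
  s22 <- f(b * b) / n - mu2^2
  s12 <- f(a * b) / n - mu1 * mu2
  den_l <- mu1^2 + mu2^2        # luminance denominator
  den_c <- s11 + s22            # contrast denominator
  q <- matrix(1, nrow(mu1), ncol(mu1))
  i1 <- den_l != 0 & den_c == 0
  q[i1] <- 2 * mu1[i1] * mu2[i1] / den_l[i1]
  i2 <- den_l * den_c != 0
  q[i2] <- 4 * s12[i2] * mu1[i2] * mu2[i2] / (den_l[i2] * den_c[i2])
  mean(q)
}

#' @rdname uqi
#' @export
vsi <- function(v, vhat) {
  check_same_shape(v, vhat)
  mean(vapply(seq_len(dim(v)[3]), function(k)
    vsi_2d(extract_slice(v, k), extract_slice(vhat, k)),
    numeric(1)))
}

# saliency-weighted similarity on one grayscale slice; constants follow
# the published index (C1 = 1.27 for saliency, C2 = 386 for gradients on a
# 0..255 intensity scale, alpha = 0.40)
vsi_2d <- function(a, b, c1 = 1.27, c2 = 386, alpha = 0.4) {
  a255 <- a * 255; b255 <- b * 255
  vs1 <- saliency_map(a255)
  vs2 <- saliency_map(b255)
  g1 <- scharr_mag(a255)
  g2 <- scharr_mag(b255)
  s_vs <- (2 * vs1 * vs2 + c1) / (vs1^2 + vs2^2 + c1)
  s_g <- (2 * g1 * g2 + c2) / (g1^2 + g2^2 + c2)
  s <- s_vs * s_g^alpha
  wt <- pmax(vs1, vs2)
  if (sum(wt) == 0) mean(s) else sum(s * wt) / sum(wt)
}

# band-pass (log-Gabor) frequency prior times a Gaussian center prior,
# normalized to [0, 1]
saliency_map <- function(img, omega0 = 0.021, sigma_f = 1.34) {
  n <- nrow(img); m <- ncol(img)
  fu <- (seq_len(n) - 1); fu[fu > n / 2] <- fu[fu > n / 2] - n
  fv <- (seq_len(m) - 1); fv[fv > m / 2] <- fv[fv > m / 2] - m
  fr <- sqrt(outer((fu / n)^2, (fv / m)^2, "+"))
  lg <- matrix(0, n, m)
  nz <- fr > 0
  lg[nz] <- exp(-(log(fr[nz] / omega0))^2 / (2 * log(sigma_f)^2))
  sf <- Mod(stats::fft(stats::fft(img) * lg, inverse = TRUE)) / (n * m)
  cu <- (seq_len(n) - (n + 1) / 2) / n
  cv <- (seq_len(m) - (m + 1) / 2) / m
  sd_c <- 0.45
  ctr <- exp(-outer(cu^2, cv^2, "+") / sd_c^2)
  vs <- sf * ctr
  mx <- max(vs)
  if (mx > 0) vs / mx else vs
}

# Scharr gradient magnitude with replicated borders (separable 3x1 taps)
scharr_mag <- function(img) {
  smooth <- c(3, 10, 3) / 16
  diff1 <- c(1, 0, -1)
  gx <- sep_filter2_same(img, diff1, smooth)
  gy <- sep_filter2_same(img, smooth, diff1)
  sqrt(gx^2 + gy^2)
}

sep_filter2_same <- function(x, krow, kcol) {
  xp <- x[c(1, seq_len(nrow(x)), nrow(x)), c(1, seq_len(ncol(x)), ncol(x))]
  band_mat(nrow(xp), krow) %*% xp %*% t(band_mat(ncol(xp), kcol))
}

#' @rdname uqi
#' @export
ssim_volume <- function(v, vhat, cfg = loss_config()) {
  check_same_shape(v, vhat)
  mean(vapply(seq_len(dim(v)[3]), function(k)
    ssim_2d(extract_slice(v, k), extract_slice(vhat, k), cfg),
    numeric(1)))
}

#' Full evaluation report for one (ground truth, generated) pair
#'
#' Thresholds for the overlap metrics derive from the ground-truth
#' volume's quantiles only (the protocol analyzes the truth's voxel-value
#' distribution, never the generated one): `metric_threshold_q` picks the
#' quantile binarizing both volumes for IoU/F1/Dice/precision/recall;
#' `quantiles` are additionally reported as reference thresholds.
#'
#' @param v ground-truth volume.
#' @param vhat generated volume, same shape.
#' @param quantiles quantiles whose truth-derived thresholds the report
#'   lists (labelled Q1/Q2/Q3 when they match quartiles).
#' @param metric_threshold_q quantile used for the overlap metrics.
#' @param cfg loss/SSIM configuration.
#' @param include_vsi compute the (comparatively heavy) saliency index.
#' @return a `voxgan_metric_report` list: `iou`, `dice`, `f1`,
#'   `precision`, `recall`, `l1`, `psnr`, `uqi`, `vsi`, `ssim`,
#'   `thresholds`, `metric_threshold`, `quantile_labels`.
#' @export
evaluate_pair <- function(v, vhat, quantiles = c(0.25, 0.75),
                          metric_threshold_q = 0.25, cfg = loss_config(),
                          include_vsi = TRUE) {
  check_same_shape(v, vhat)
  thresholds <- vapply(quantiles, function(q) quantile_threshold(v, q),
                       numeric(1))
  labels <- vapply(quantiles, quantile_label, character(1))
  names(thresholds) <- labels
  t_metric <- quantile_threshold(v, metric_threshold_q)
  om <- overlap_metrics(confusion_counts(v, vhat, t_metric))
  structure(c(om,
              list(l1 = distance_loss(v, vhat),
                   psnr = psnr(v, vhat),
                   uqi = uqi(v, vhat),
                   vsi = if (include_vsi) vsi(v, vhat) else NA_real_,
                   ssim = ssim_volume(v, vhat, cfg),
                   thresholds = thresholds,
                   metric_threshold = t_metric,
                   metric_threshold_q = metric_threshold_q,
                   quantile_labels = labels)),
            class = "voxgan_metric_report")
}

quantile_label <- function(q) {
  if (isTRUE(all.equal(q, 0.25))) "Q1"
  else if (isTRUE(all.equal(q, 0.5))) "Q2"
  else if (isTRUE(all.equal(q, 0.75))) "Q3"
  else sprintf("q%.4g", q)
}

#' @export
print.voxgan_metric_report <- function(x, ...) {
  cat("<voxgan_metric_report>\n")
  cat(sprintf("  overlap at t = %.4f (q = %.3g): iou %.4f dice %.4f f1 %.4f\n",
              x$metric_threshold, x$metric_threshold_q, x$iou, x$dice, x$f1))
  cat(sprintf("  l1 %.4f  psnr %s dB  uqi %.4f  vsi %s  ssim %.4f\n",
              x$l1, format(x$psnr, digits = 5), x$uqi,
              if (is.na(x$vsi)) "NA" else sprintf("%.4f", x$vsi), x$ssim))
  invisible(x)
}

#' Overlap metrics across a Q1-to-Q3 threshold sweep
#'
#' Evaluates IoU, F1 and Dice at `n` evenly spaced quantiles between
#' `q_lo` and `q_hi` (defaults give 25%, 37.5%, 50%, 62.5%, 75%), with
#' thresholds taken from the ground-truth quantiles.
#'
#' @param v,vhat ground-truth and generated volumes.
#' @param q_lo,q_hi sweep endpoints (quantiles).
#' @param n number of sweep points, >= 2.
#' @return `data.frame` with columns `quantile`, `threshold`, `iou`,
#'   `f1`, `dice`.
#' @export
threshold_sweep <- function(v, vhat, q_lo = 0.25, q_hi = 0.75, n = 5L) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  check_same_shape(v, vhat)
  qs <- seq(q_lo, q_hi, length.out = n)
  rows <- lapply(qs, function(q) {
    t <- quantile_threshold(v, q)
    om <- overlap_metrics(confusion_counts(v, vhat, t))
    data.frame(quantile = q, threshold = t, iou = om$iou, f1 = om$f1,
               dice = om$dice)
  })
  do.call(rbind, rows)
}
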