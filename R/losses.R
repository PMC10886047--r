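#' Configure the composite reconstruction and adversarial losses
#'
#' The generator objective is `l_adv_g + alpha * l_recon` with
#' `l_recon = l_dist + l_feat + l_sim`:
#' * `l_dist` -- mean absolute voxel difference (L1);
#' * `l_feat` -- 1 minus the threshold-averaged Jaccard overlap of
#'   high-value voxel sets (voxels `>= t_s`), emphasizing the anatomy's
#'   high-density regions;
#' * `l_sim` -- 1 minus the mean slice-wise SSIM along z.
#'
#' The adversarial terms are least-squares with targets 1/2 (real) and 0
#' (fake); the generator drives fake scores toward 1/2. The conventional
#' LSGAN targets (1/0/1) are available via `lsgan_targets = "standard"`.
#'
#' @param alpha weight on the reconstruction loss in the generator
#'   objective; default 33.
#' @param thresholds strictly increasing feature-loss thresholds `t_s` in
#'   `[0, 1]`.
#' @param normalize_feature_by_nr divide the feature loss by the number of
#'   thresholds so it stays in `[0, 1]` (default); `FALSE` gives the raw sum
#'   over thresholds.
#' @param ssim_window odd SSIM window size (>= 3).
#' @param ssim_sigma Gaussian window sd.
#' @param ssim_k1,ssim_k2 SSIM stability constants; `C1 = k1^2`,
#'   `C2 = k2^2` at dynamic range 1.
#' @param soft_sharpness sigmoid sharpness tau of the differentiable
#'   feature-loss surrogate used during training (the reported value is
#'   always the hard-indicator loss).
#' @param lsgan_targets `"as_printed"` (1/2, 0, 1/2) or `"standard"`
#'   (1, 0, 1).
#' @return a `voxgan_loss_config` list.
#' @export
loss_config <- function(alpha = 33,
                        thresholds = c(0.2, 0.4, 0.6, 0.8),
                        normalize_feature_by_nr = TRUE,
                        ssim_window = 11L,
                        ssim_sigma = 1.5,
                        ssim_k1 = 0.01,
                        ssim_k2 = 0.03,
                        soft_sharpness = 50,
                        lsgan_targets = c("as_printed", "standard")) {
  lsgan_targets <- match.arg(lsgan_targets)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (length(thresholds) < 1L || any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  ssim_window <- as.integer(ssim_window)
  if (ssim_window < 3L || ssim_window %% 2L == 0L)
    stop("ssim_window must be odd and >= 3", call. = FALSE)
  if (ssim_sigma <= 0) stop("ssim_sigma must be > 0", call. = FALSE)
  if (soft_sharpness <= 0) stop("soft_sharpness must be > 0", call. = FALSE)
  structure(list(alpha = alpha, thresholds = thresholds,
                 normalize_feature_by_nr = isTRUE(normalize_feature_by_nr),
                 ssim_window = ssim_window, ssim_sigma = ssim_sigma,
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 soft_sharpness = soft_sharpness,
                 lsgan_targets = lsgan_targets),
            class = "voxgan_loss_config")
}

#' Distance loss: mean absolute voxel difference
#'
#' @param v,vhat volumes of identical shape.
#' @return scalar in `[0, 1]` for `[0, 1]` volumes; 0 iff `v == vhat`.
#' @export
distance_loss <- function(v, vhat) {
  check_same_shape(v, vhat)
  mean(abs(unclass(v) - unclass(vhat)))
}

# Jaccard overlap of {>= t} sets; empty union counts as perfect agreement
hard_overlap <- function(v, vhat, t) {
  a <- unclass(v) >= t
  b <- unclass(vhat) >= t
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

#' Feature loss: high-value voxel overlap across thresholds
#'
#' For each threshold `t_s` the Jaccard overlap
#' `|v >= t_s AND vhat >= t_s| / |v >= t_s OR vhat >= t_s|` is computed
#' (hard indicators, `>=` comparisons); a threshold at which neither volume
#' has any voxel above `t_s` contributes overlap 1 (perfect agreement on
#' absence). The loss is `sum_s (1 - overlap_s)`, divided by the number of
#' thresholds when `normalize_feature_by_nr` is set.
#'
#' @param v,vhat volumes of identical shape.
#' @param cfg a [loss_config()].
#' @return scalar; in `[0, 1]` when normalized. Symmetric in its arguments.
#' @export
feature_loss <- function(v, vhat, cfg = loss_config()) {
  check_same_shape(v, vhat)
  miss <- vapply(cfg$thresholds,
                 function(t) 1 - hard_overlap(v, vhat, t), numeric(1))
  if (cfg$normalize_feature_by_nr) mean(miss) else sum(miss)
}

#' Differentiable surrogate of the feature loss
#'
#' Hard indicators have zero gradient almost everywhere, so training
#' replaces `I(x >= t)` with `sigmoid((x - t) * sharpness)`; intersection
#' and union become their product t-norm/conorm. As `sharpness -> Inf` the
#' surrogate converges to [feature_loss()].
#'
#' @inheritParams feature_loss
#' @param sharpness sigmoid sharpness tau; defaults to `cfg$soft_sharpness`.
#' @export
soft_feature_loss <- function(v, vhat, cfg = loss_config(),
                              sharpness = cfg$soft_sharpness) {
  check_same_shape(v, vhat)
  x <- as.vector(unclass(v)); y <- as.vector(unclass(vhat))
  miss <- vapply(cfg$thresholds, function(t) {
    a <- plogis((x - t) * sharpness)
    b <- plogis((y - t) * sharpness)
    inter <- sum(a * b)
    uni <- sum(a + b - a * b)
    if (uni == 0) 0 else 1 - inter / uni
  }, numeric(1))
  if (cfg$normalize_feature_by_nr) mean(miss) else sum(miss)
}

#' Structural similarity between two 2D slices
#'
#' Mean local SSIM with a Gaussian window (valid region, dynamic range 1,
#' `C1 = k1^2`, `C2 = k2^2`). If the image is smaller than the window, the
#' window shrinks to the largest odd size that fits.
#'
#' @param a,b matrices of identical shape with values in `[0, 1]`.
#' @param cfg a [loss_config()] supplying window, sigma and constants.
#' @return scalar in `[-1, 1]`; 1 iff `a == b` (within 1e-7).
#' @export
ssim_2d <- function(a, b, cfg = loss_config()) {
  if (!identical(dim(a), dim(b)))
    stop("image shapes differ", call. = FALSE)
  mean(ssim_map_2d(a, b, cfg))
}

# local SSIM map over the valid filtering region
ssim_map_2d <- function(a, b, cfg) {
  win <- effective_window(cfg$ssim_window, dim(a))
  g <- gaussian_kernel_1d(win, cfg$ssim_sigma)
  f <- function(x) sep_filter2_valid(x, g)
  c1 <- cfg$ssim_k1^2; c2 <- cfg$ssim_k2^2
  mu1 <- f(a); mu2 <- f(b)
  s11 <- f(a * a) - mu1 * mu1
  s22 <- f(b * b) - mu2 * mu2
  s12 <- f(a * b) - mu1 * mu2
  ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1 * mu1 + mu2 * mu2 + c1) * (s11 + s22 + c2))
}

effective_window <- function(win, d) {
  m <- min(d[1], d[2])
  if (win > m) win <- if (m %% 2L == 1L) m else m - 1L
  as.integer(win)
}

gaussian_kernel_1d <- function(win, sigma) {
  x <- seq_len(win) - (win + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable valid-mode 2D filtering via banded matrices: B_r %*% x %*% t(B_c)
sep_filter2_valid <- function(x, g) {
  band_mat(nrow(x), g) %*% x %*% t(band_mat(ncol(x), g))
}

band_mat <- function(n, g) {
  w <- length(g)
  m <- matrix(0, n - w + 1L, n)
  for (i in seq_len(n - w + 1L)) m[i, i:(i + w - 1L)] <- g
  m
}

#' Similarity loss: 1 minus mean slice-wise SSIM along z
#'
#' @inheritParams feature_loss
#' @return scalar in `[0, 2]`; 0 iff `v == vhat` (within tolerance).
#' @export
similarity_loss <- function(v, vhat, cfg = loss_config()) {
  check_same_shape(v, vhat)
  h <- dim(v)[3]
  s <- vapply(seq_len(h),
              function(k) ssim_2d(extract_slice(v, k),
                                  extract_slice(vhat, k), cfg),
              numeric(1))
  1 - mean(s)
}

#' Composite reconstruction loss
#'
#' Computes the three reconstruction terms on one volume pair and their sum
#' `l_recon = l_dist + l_feat + l_sim`. The adversarial fields of the
#' returned breakdown are `NA`; training fills them.
#'
#' @inheritParams feature_loss
#' @return a `voxgan_loss_breakdown` with fields `l_dist`, `l_feat`,
#'   `l_sim`, `l_recon`, `l_adv_g`, `l_g_total`, `l_d`.
#' @export
reconstruction_loss <- function(v, vhat, cfg = loss_config()) {
  b <- loss_breakdown(l_dist = distance_loss(v, vhat),
                      l_feat = feature_loss(v, vhat, cfg),
                      l_sim = similarity_loss(v, vhat, cfg))
  b
}

loss_breakdown <- function(l_dist = NA_real_, l_feat = NA_real_,
                           l_sim = NA_real_, l_adv_g = NA_real_,
                           l_d = NA_real_, alpha = NA_real_) {
  l_recon <- l_dist + l_feat + l_sim
  l_g_total <- if (is.na(l_adv_g)) NA_real_ else l_adv_g + alpha * l_recon
  structure(list(l_dist = l_dist, l_feat = l_feat, l_sim = l_sim,
                 l_recon = l_recon, l_adv_g = l_adv_g,
                 l_g_total = l_g_total, l_d = l_d),
            class = "voxgan_loss_breakdown")
}

#' @export
print.voxgan_loss_breakdown <- function(x, ...) {
  cat("<voxgan_loss_breakdown>\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Least-squares adversarial losses
#'
#' `generator_adversarial_loss` is `mean((D(fake) - 1/2)^2)`: the generator
#' drives the discriminator's score on fakes toward 1/2.
#' `discriminator_loss` is `mean((D(real) - 1/2)^2) + mean(D(fake)^2)`,
#' minimized at real scores 1/2 and fake scores 0. With
#' `lsgan_targets = "standard"` the conventional 1/0/1 targets are used.
#'
#' @param d_fake,d_real discriminator scores in `[0, 1]` (vectors average
#'   as a minibatch expectation).
#' @param cfg a [loss_config()] (only `lsgan_targets` is consulted).
#' @return scalar loss, >= 0.
#' @export
generator_adversarial_loss <- function(d_fake, cfg = loss_config()) {
  tgt <- if (cfg$lsgan_targets == "standard") 1 else 0.5
  mean((d_fake - tgt)^2)
}

#' @rdname generator_adversarial_loss
#' @export
discriminator_loss <- function(d_real, d_fake, cfg = loss_config()) {
  tgt <- if (cfg$lsgan_targets == "standard") 1 else 0.5
  mean((d_real - tgt)^2) + mean(d_fake^2)
}
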