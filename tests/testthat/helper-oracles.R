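# shared fixtures and independent brute-force oracles

rand_vol <- function(d = c(4L, 4L, 4L)) {
  if (length(d) == 1L) d <- rep(d, 3L)
  as_volume(array(runif(prod(d)), d))
}

# the 2x2x1 worked example used across loss/metric tests (raster order:
# x fastest)
example_pair <- function() {
  v <- as_volume(array(c(0.8, 0.2, 0.6, 0.1), c(2, 2, 1)))
  vhat <- as_volume(array(c(0.7, 0.1, 0.2, 0.9), c(2, 2, 1)))
  list(v = v, vhat = vhat)
}

# per-voxel double-loop enumeration of the feature loss (hard indicators)
oracle_feature_loss <- function(v, vhat, thresholds, normalize = TRUE) {
  va <- as.vector(unclass(v)); vb <- as.vector(unclass(vhat))
  miss <- numeric(0)
  for (t in thresholds) {
    inter <- 0L; uni <- 0L
    for (m in seq_along(va)) {
      a <- va[m] >= t; b <- vb[m] >= t
      if (a && b) inter <- inter + 1L
      if (a || b) uni <- uni + 1L
    }
    ov <- if (uni == 0L) 1 else inter / uni
    miss <- c(miss, 1 - ov)
  }
  if (normalize) mean(miss) else sum(miss)
}

# per-voxel double-loop confusion counts (strict >, standard convention)
oracle_confusion <- function(v, vhat, t) {
  va <- as.vector(unclass(v)); vb <- as.vector(unclass(vhat))
  tp <- fp <- fn <- tn <- 0L
  for (m in seq_along(va)) {
    a <- va[m] > t; b <- vb[m] > t
    if (a && b) tp <- tp + 1L
    else if (!a && b) fp <- fp + 1L
    else if (a && !b) fn <- fn + 1L
    else tn <- tn + 1L
  }
  n <- length(va)
  list(tp = tp / n, fp = fp / n, fn = fn / n, tn = tn / n)
}

# direct-formula SSIM: explicit loop over window positions, Gaussian
# weighted moments computed from first principles
oracle_ssim <- function(a, b, win = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  m <- min(dim(a))
  if (win > m) win <- if (m %% 2L == 1L) m else m - 1L
  x <- seq_len(win) - (win + 1) / 2
  g1 <- exp(-x^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  wmat <- outer(g1, g1)
  c1 <- k1^2; c2 <- k2^2
  vals <- c()
  for (i in seq_len(nrow(a) - win + 1L)) {
    for (j in seq_len(ncol(a) - win + 1L)) {
      pa <- a[i:(i + win - 1L), j:(j + win - 1L)]
      pb <- b[i:(i + win - 1L), j:(j + win - 1L)]
      mu1 <- sum(wmat * pa); mu2 <- sum(wmat * pb)
      s11 <- sum(wmat * pa * pa) - mu1^2
      s22 <- sum(wmat * pb * pb) - mu2^2
      s12 <- sum(wmat * pa * pb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
                  ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)))
    }
  }
  mean(vals)
}

# desk-scale network configs used by the lighter tests
tiny_gen_cfg <- function(res = 8L)
  generator_config(depth_down = 2L, depth_mid = 1L, base_channels = 4L,
                   lffb_branches = c(1L, 3L), out_resolution = res)

tiny_disc_cfg <- function(res = 8L)
  discriminator_config(depth = 2L, base_channels = 4L, in_resolution = res)

tiny_phantom_pair <- function(kind = "sphere", res = 8L, seed = 1L,
                              mode = "full_stack") {
  make_phantom(phantom_spec(kind = kind, resolution = res, noise_sd = 0.01,
                            deform = 0.02, seed = seed),
               condition_mode = mode)
}

# smoke-scale network width used by the training checks: narrow enough to
# train on one CPU in minutes at 16^3
smoke_gen_cfg <- function(res = 16L)
  generator_config(base_channels = 8L, out_resolution = res)

smoke_disc_cfg <- function(res = 16L)
  discriminator_config(base_channels = 8L, in_resolution = res)
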