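test_that("distance loss matches hand enumeration and its contract", {
  ex <- example_pair()
  expect_equal(distance_loss(ex$v, ex$vhat), 0.35)
  v1 <- as_volume(array(1, c(3, 3, 3)))
  v0 <- as_volume(array(0, c(3, 3, 3)))
  expect_equal(distance_loss(v1, v0), 1)
  expect_equal(distance_loss(v1, v1), 0)
  expect_error(distance_loss(v1, rand_vol(c(2, 2, 2))), "shapes differ")
})

test_that("feature loss matches hand enumeration and handles empty unions", {
  ex <- example_pair()
  cfg1 <- loss_config(thresholds = 0.5)
  expect_equal(feature_loss(ex$v, ex$vhat, cfg1), 1 - 1 / 3)
  v1 <- as_volume(array(1, c(2, 2, 2)))
  v0 <- as_volume(array(0, c(2, 2, 2)))
  expect_equal(feature_loss(v1, v0, cfg1), 1)
  expect_equal(feature_loss(v1, v1, loss_config()), 0)
  # empty union at every threshold: agreement on absence is not penalized
  lo <- as_volume(array(0.05, c(2, 2, 2)))
  expect_equal(feature_loss(lo, lo, loss_config(thresholds = c(0.5, 0.9))), 0)
  # unnormalized variant sums over thresholds
  cfg2 <- loss_config(thresholds = c(0.5, 0.95), normalize_feature_by_nr = FALSE)
  expect_equal(feature_loss(ex$v, ex$vhat, cfg2),
               oracle_feature_loss(ex$v, ex$vhat, c(0.5, 0.95), FALSE))
})

test_that("feature loss equals brute-force enumeration on random pairs", {
  withr::local_seed(4)
  cfg <- loss_config()
  for (i in 1:25) {
    d <- sample(2:4, 3, replace = TRUE)
    v <- rand_vol(d); vhat <- rand_vol(d)
    expect_equal(feature_loss(v, vhat, cfg),
                 oracle_feature_loss(v, vhat, cfg$thresholds), tolerance = 0)
  }
})

test_that("distance and feature losses are symmetric with bounded ranges", {
  withr::local_seed(5)
  cfg <- loss_config()
  for (i in 1:30) {
    v <- rand_vol(c(5, 4, 3)); vhat <- rand_vol(c(5, 4, 3))
    ld <- distance_loss(v, vhat)
    lf <- feature_loss(v, vhat, cfg)
    expect_identical(ld, distance_loss(vhat, v))
    expect_identical(lf, feature_loss(vhat, v, cfg))
    expect_gte(ld, 0); expect_lte(ld, 1)
    expect_gte(lf, 0); expect_lte(lf, 1)
    ls <- similarity_loss(v, vhat, cfg)
    expect_gte(ls, 0); expect_lte(ls, 2)
  }
})

test_that("ssim_2d matches an independently coded direct formula", {
  withr::local_seed(6)
  cfg <- loss_config()
  for (i in 1:20) {
    a <- matrix(runif(15 * 15), 15)
    b <- if (i %% 4 == 0) a + matrix(rnorm(225, 0, 0.05), 15) else
      matrix(runif(225), 15)
    b <- pmin(pmax(b, 0), 1)
    expect_equal(ssim_2d(a, b, cfg), oracle_ssim(a, b), tolerance = 1e-6)
  }
})

test_that("SSIM self-identity and the constant-image closed form hold", {
  withr::local_seed(7)
  cfg <- loss_config()
  a <- matrix(runif(256), 16)
  expect_equal(ssim_2d(a, a, cfg), 1, tolerance = 1e-7)
  half <- matrix(0.5, 16, 16)
  expect_equal(ssim_2d(half, half, cfg), 1, tolerance = 1e-12)
  c1 <- cfg$ssim_k1^2
  expect_equal(ssim_2d(matrix(0, 16, 16), matrix(1, 16, 16), cfg),
               c1 / (1 + c1), tolerance = 1e-12)
})

test_that("similarity loss vanishes iff equal and hits its closed form", {
  withr::local_seed(8)
  cfg <- loss_config()
  v <- rand_vol(c(16, 16, 4))
  expect_lt(similarity_loss(v, v, cfg), 1e-6)
  v0 <- as_volume(array(0, c(16, 16, 2)))
  v1 <- as_volume(array(1, c(16, 16, 2)))
  c1 <- cfg$ssim_k1^2
  expect_equal(similarity_loss(v0, v1, cfg), 1 - c1 / (1 + c1),
               tolerance = 1e-12)
})

test_that("reconstruction loss sums its components", {
  withr::local_seed(9)
  cfg <- loss_config()
  v <- rand_vol(c(12, 12, 6)); vhat <- rand_vol(c(12, 12, 6))
  b <- reconstruction_loss(v, vhat, cfg)
  expect_equal(b$l_recon, b$l_dist + b$l_feat + b$l_sim)
  expect_gte(b$l_recon, max(b$l_dist, b$l_feat, b$l_sim))
  expect_equal(b$l_dist, distance_loss(v, vhat))
  same <- reconstruction_loss(v, v, cfg)
  expect_lt(same$l_recon, 1e-6)
})

test_that("adversarial losses hit the printed targets", {
  cfg <- loss_config()
  expect_equal(generator_adversarial_loss(0.5, cfg), 0)
  expect_equal(generator_adversarial_loss(0, cfg), 0.25)
  expect_equal(generator_adversarial_loss(1, cfg), 0.25)
  expect_equal(discriminator_loss(0.5, 0, cfg), 0)
  expect_equal(discriminator_loss(1, 1, cfg), 1.25)
  expect_equal(discriminator_loss(0, 0.5, cfg), 0.5)
  std <- loss_config(lsgan_targets = "standard")
  expect_equal(generator_adversarial_loss(1, std), 0)
  expect_equal(discriminator_loss(1, 0, std), 0)
})

test_that("soft feature surrogate converges to the hard loss in sharpness", {
  withr::local_seed(10)
  cfg <- loss_config()
  taus <- c(10, 50, 250)
  gaps <- matrix(NA_real_, 20, length(taus))
  for (i in 1:20) {
    v <- rand_vol(c(6, 6, 6)); vhat <- rand_vol(c(6, 6, 6))
    hard <- feature_loss(v, vhat, cfg)
    for (j in seq_along(taus))
      gaps[i, j] <- abs(soft_feature_loss(v, vhat, cfg, taus[j]) - hard)
  }
  mx <- apply(gaps, 2, max)
  expect_lt(mx[3], mx[1])
  expect_true(all(diff(mx) < 0))
})

test_that("loss gradients with respect to the generated volume are finite", {
  withr::local_seed(11)
  cfg <- loss_config(ssim_window = 5L)
  v <- unclass(rand_vol(c(8, 8, 4)))
  vhat <- unclass(rand_vol(c(8, 8, 4)))
  tp <- voxgan:::ad_tape()
  fake <- voxgan:::ad_leaf(tp, array(vhat, c(8, 8, 4, 1)))
  rl <- voxgan:::recon_loss_nodes(tp, array(v, c(8, 8, 4, 1)), fake, cfg)
  voxgan:::ad_backward(tp, rl$l_recon)
  expect_true(all(is.finite(fake$grad)))
  expect_gt(max(abs(fake$grad)), 0)
})
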