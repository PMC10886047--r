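test_that("config validation enforces divisibility and symmetry", {
  expect_error(generator_config(out_resolution = 12L, depth_down = 3L),
               "divisible")
  expect_error(generator_config(dropout = 1), "dropout")
  expect_error(generator_config(lffb_branches = c(2L, 3L)), "odd")
  expect_error(discriminator_config(in_resolution = 8L, depth = 4L),
               "divisible")
  cfg <- generator_config(out_resolution = 16L)
  expect_identical(cfg$depth_up, cfg$depth_down)
})

test_that("generator output obeys shape and range contracts", {
  pp <- tiny_phantom_pair()
  G <- build_generator(tiny_gen_cfg(), seed = 2L)
  v <- generator_forward(G, pp$condition)
  expect_identical(dim(v), c(8L, 8L, 8L))
  expect_true(all(unclass(v) > 0 & unclass(v) < 1))
  validate_volume(v)
  # zero conditioning still yields a finite in-range volume
  z <- image_set(array(0, c(8, 8, 8)))
  vz <- generator_forward(G, z)
  expect_true(all(is.finite(unclass(vz))))
})

test_that("announced layer shapes match the measured shapes", {
  for (cfg in list(tiny_gen_cfg(),
                   generator_config(out_resolution = 16L,
                                    base_channels = 6L))) {
    pp <- tiny_phantom_pair(res = cfg$out_resolution[1])
    G <- build_generator(cfg, seed = 1L)
    v <- generator_forward(G, pp$condition, return_shapes = TRUE)
    measured <- attr(v, "shapes")
    announced <- generator_shapes(cfg)
    for (nm in names(announced))
      expect_identical(as.integer(measured[[nm]]),
                       as.integer(announced[[nm]]),
                       label = paste("shape of", nm))
  }
})

test_that("stride arithmetic gives the documented bottleneck extents", {
  cfg <- generator_config(depth_down = 3L, out_resolution = 32L,
                          base_channels = 4L, depth_mid = 1L)
  expect_identical(generator_shapes(cfg)$down3[1:3], rep(4L, 3)) # 32 / 2^3
  dcfg <- discriminator_config(depth = 4L, in_resolution = 32L,
                               base_channels = 4L)
  expect_identical(as.integer(dcfg$in_resolution %/% 2^dcfg$depth),
                   rep(2L, 3)) # 32 / 2^4
})

test_that("same config and seed build identical parameters", {
  cfg <- tiny_gen_cfg()
  G1 <- build_generator(cfg, seed = 9L)
  G2 <- build_generator(cfg, seed = 9L)
  expect_identical(G1$params, G2$params)
  G3 <- build_generator(cfg, seed = 10L)
  expect_false(identical(G1$params, G3$params))
  dcfg <- tiny_disc_cfg()
  D1 <- build_discriminator(dcfg, seed = 9L)
  D2 <- build_discriminator(dcfg, seed = 9L)
  expect_identical(D1$params, D2$params)
})

test_that("evaluation-mode forwards are deterministic, dropout varies them", {
  pp <- tiny_phantom_pair()
  cfg <- tiny_gen_cfg()
  cfg$dropout <- 0.5
  G <- build_generator(cfg, seed = 4L)
  v1 <- generator_forward(G, pp$condition)
  v2 <- generator_forward(G, pp$condition)
  expect_identical(unclass(v1), unclass(v2))
  set.seed(1); t1 <- generator_forward(G, pp$condition, train = TRUE)
  set.seed(2); t2 <- generator_forward(G, pp$condition, train = TRUE)
  expect_false(identical(unclass(t1), unclass(t2)))
})

test_that("discriminator scores lie strictly inside (0, 1)", {
  pp <- tiny_phantom_pair()
  D <- build_discriminator(tiny_disc_cfg(), seed = 5L)
  p <- discriminator_forward(D, pp$condition, pp$truth)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_error(discriminator_forward(D, pp$condition, rand_vol(c(4, 4, 4))),
               "shapes differ")
})

test_that("one optimization step moves parameters in every layer group", {
  pp <- tiny_phantom_pair()
  cfg <- tiny_gen_cfg()
  G <- build_generator(cfg, seed = 6L)
  st <- train(list(pp), cfg, tiny_disc_cfg(),
              loss_config(ssim_window = 5L),
              train_config(steps = 1L, seed = 6L, adversarial = FALSE))
  groups <- list(lffb = "^lffb_", down = "^down", mid = "^mid",
                 up = "^up", out = "^out_")
  Gref <- build_generator(cfg, st$train_cfg$seed + 1L)  # train's init seed
  for (gname in names(groups)) {
    nms <- grep(groups[[gname]], names(st$G$params), value = TRUE)
    delta <- vapply(nms, function(nm)
      max(abs(st$G$params[[nm]] - Gref$params[[nm]])), numeric(1))
    expect_gt(max(delta), 0, label = paste("group", gname))
  }
})

test_that("sparse conditioning drives the same architecture", {
  pp <- tiny_phantom_pair(mode = "sparse_slices")
  expect_lt(dim(pp$condition$slices)[3], 8L)
  G <- build_generator(tiny_gen_cfg(), seed = 2L)
  v <- generator_forward(G, pp$condition)
  expect_identical(dim(v), c(8L, 8L, 8L))
})
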