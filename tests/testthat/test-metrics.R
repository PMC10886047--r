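test_that("confusion counts match hand enumeration on the worked example", {
  ex <- example_pair()
  cc <- confusion_counts(ex$v, ex$vhat, 0.5)
  expect_equal(cc$tp, 0.25)
  expect_equal(cc$fp, 0.25)
  expect_equal(cc$fn, 0.25)
  expect_equal(cc$tn, 0.25)
})

test_that("confusion counts equal brute-force enumeration on random pairs", {
  withr::local_seed(12)
  for (i in 1:25) {
    d <- sample(2:4, 3, replace = TRUE)
    v <- rand_vol(d); vhat <- rand_vol(d)
    t <- runif(1)
    cc <- confusion_counts(v, vhat, t)
    orc <- oracle_confusion(v, vhat, t)
    expect_equal(cc[c("tp", "fp", "fn", "tn")], orc, tolerance = 0)
  }
})

test_that("standard counts partition to one; identity has no errors", {
  withr::local_seed(13)
  for (i in 1:30) {
    v <- rand_vol(c(5, 5, 3)); vhat <- rand_vol(c(5, 5, 3))
    cc <- confusion_counts(v, vhat, runif(1))
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 1)
  }
  v <- rand_vol(c(4, 4, 4))
  cc <- confusion_counts(v, v, 0.5)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
})

test_that("the as_printed convention reports the literal FN formula", {
  ex <- example_pair()
  lit <- confusion_counts(ex$v, ex$vhat, 0.5, convention = "as_printed")
  std <- confusion_counts(ex$v, ex$vhat, 0.5)
  expect_equal(lit$fn, std$tn)  # printed FN counts v<=t & vhat<=t
  expect_equal(lit$tp, std$tp)
  expect_equal(lit$fp, std$fp)
  expect_error(overlap_metrics(lit), "as_printed")
})

test_that("overlap metrics satisfy their formulas and algebra", {
  ex <- example_pair()
  om <- overlap_metrics(confusion_counts(ex$v, ex$vhat, 0.5))
  expect_equal(om$iou, 1 / 3)
  expect_equal(om$dice, 0.5)
  expect_equal(om$f1, 0.5)
  withr::local_seed(14)
  for (i in 1:30) {
    v <- rand_vol(c(4, 5, 3)); vhat <- rand_vol(c(4, 5, 3))
    om <- overlap_metrics(confusion_counts(v, vhat, runif(1)))
    expect_equal(om$dice, 2 * om$iou / (1 + om$iou), tolerance = 1e-9)
    expect_equal(om$f1, om$dice, tolerance = 1e-9)
  }
  perfect <- overlap_metrics(confusion_counts(ex$v, ex$v, 0.5))
  expect_equal(unlist(perfect), c(iou = 1, dice = 1, f1 = 1,
                                  precision = 1, recall = 1))
  # all-background agreement: 0/0 cells defined as 1
  z <- as_volume(array(0, c(3, 3, 3)))
  expect_equal(overlap_metrics(confusion_counts(z, z, 0.5))$iou, 1)
})

test_that("quantile thresholds interpolate and are monotone in q", {
  v <- as_volume(array(seq(0, 1, length.out = 101), c(101, 1, 1)))
  expect_equal(quantile_threshold(v, 0.75), 0.75)
  expect_equal(quantile_threshold(v, 0.25), 0.25)
  const <- as_volume(array(0.4, c(4, 4, 4)))
  for (q in c(0.1, 0.5, 0.9))
    expect_equal(quantile_threshold(const, q), 0.4)
  withr::local_seed(15)
  w <- rand_vol(c(6, 6, 6))
  qs <- seq(0.05, 0.95, by = 0.05)
  ts <- vapply(qs, function(q) quantile_threshold(w, q), numeric(1))
  expect_true(all(diff(ts) >= 0))
  expect_error(quantile_threshold(w, 0), "in \\(0, 1\\)")
  expect_error(quantile_threshold(w, 1), "in \\(0, 1\\)")
})

test_that("psnr hits its closed forms and the infinity sentinel", {
  v0 <- as_volume(array(0, c(4, 4, 4)))
  v01 <- as_volume(array(0.1, c(4, 4, 4)))
  v1 <- as_volume(array(1, c(4, 4, 4)))
  expect_equal(psnr(v0, v01), 20)        # MSE 0.01
  expect_equal(psnr(v0, v1), 0)          # MSE 1
  expect_identical(psnr(v0, v0), Inf)
})

test_that("similarity indices equal one for identical volumes", {
  withr::local_seed(16)
  pp <- tiny_phantom_pair(kind = "vertebra", res = 12L)
  v <- pp$truth
  expect_equal(uqi(v, v), 1)
  expect_equal(vsi(v, v), 1)
  expect_equal(ssim_volume(v, v), 1, tolerance = 1e-7)
  const <- as_volume(array(0.3, c(8, 8, 2)))
  expect_equal(uqi(const, const), 1)
  expect_equal(vsi(const, const), 1)
})

test_that("uqi degrades monotonically with heavier corruption", {
  withr::local_seed(17)
  v <- make_phantom(phantom_spec(kind = "vertebra", resolution = 16L,
                                 seed = 3L))$truth
  tiny <- as_volume(array(pmin(pmax(unclass(v) +
                                      rnorm(length(v), 0, 0.005), 0), 1),
                          dim(v)))
  noise <- as_volume(array(runif(length(v)), dim(v)))
  expect_lt(uqi(v, noise), uqi(v, tiny))
})

test_that("evaluation reports derive thresholds from the ground truth only", {
  withr::local_seed(18)
  pp <- tiny_phantom_pair(kind = "vertebra", res = 12L)
  v <- pp$truth
  # generated volume with a deliberately different distribution
  vhat <- as_volume(unclass(v) * 0.5)
  rep <- evaluate_pair(v, vhat, include_vsi = FALSE)
  expect_equal(rep$metric_threshold, quantile_threshold(v, 0.25))
  expect_equal(unname(rep$thresholds),
               c(quantile_threshold(v, 0.25), quantile_threshold(v, 0.75)))
  expect_identical(rep$quantile_labels, c("Q1", "Q3"))
  # identity report
  ident <- evaluate_pair(v, v)
  expect_equal(ident$iou, 1); expect_equal(ident$dice, 1)
  expect_equal(ident$f1, 1); expect_equal(ident$l1, 0)
  expect_identical(ident$psnr, Inf)
  expect_equal(ident$uqi, 1); expect_equal(ident$vsi, 1)
  expect_equal(ident$ssim, 1, tolerance = 1e-7)
  expect_equal(ident$dice, 2 * ident$iou / (1 + ident$iou))
})

test_that("complement volumes produce empty overlap at the median", {
  withr::local_seed(19)
  v <- rand_vol(c(6, 6, 6))
  comp <- as_volume(1 - unclass(v))
  t <- quantile_threshold(v, 0.5)
  om <- overlap_metrics(confusion_counts(v, comp, t))
  expect_equal(om$iou, 0)
})

test_that("threshold sweep emits the documented quantile grid", {
  withr::local_seed(20)
  pp <- tiny_phantom_pair(kind = "vertebra", res = 12L)
  v <- pp$truth
  sw <- threshold_sweep(v, v)
  expect_identical(nrow(sw), 5L)
  expect_equal(sw$quantile, c(0.25, 0.375, 0.5, 0.625, 0.75))
  expect_true(all(sw$iou == 1))
  expect_true(all(diff(sw$threshold) >= 0))
  expect_error(threshold_sweep(v, v, n = 1L), ">= 2")
})
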