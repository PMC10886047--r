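test_that("volume construction enforces the voxel contract", {
  expect_error(as_volume(array(2, c(2, 2, 2))), "outside \\[0, 1\\]")
  expect_error(as_volume(array(NA_real_, c(2, 2, 2))), "non-finite")
  expect_error(as_volume(matrix(0.5, 2, 2)), "3 dimensions")
  v <- as_volume(array(0.5, c(3, 4, 5)), spacing = c(1, 1, 2))
  expect_identical(dim(v), c(3L, 4L, 5L))
  expect_identical(attr(v, "spacing"), c(1, 1, 2))
})

test_that("NIfTI round-trip is value-exact for floating storage", {
  withr::local_seed(1)
  for (i in 1:10) {
    d <- sample(4:12, 3, replace = TRUE)
    v <- rand_vol(d)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_volume(v, f, "nifti")
    back <- read_volume(f, "nifti")
    expect_identical(dim(back), dim(v))
    expect_identical(as.vector(unclass(back)), as.vector(unclass(v)))
  }
})

test_that("slice-stack round-trip respects the 16-bit quantization bound", {
  withr::local_seed(2)
  v <- rand_vol(c(8, 8, 8))
  d <- withr::local_tempdir()
  write_volume(v, file.path(d, "stack"), "slice_stack")
  back <- read_volume(file.path(d, "stack"), "slice_stack")
  expect_identical(dim(back), dim(v))
  expect_lte(max(abs(unclass(back) - unclass(v))), 1 / 65535)
})

test_that("slice stacks read in lexicographic order with z = slice order", {
  d <- withr::local_tempdir()
  v <- rand_vol(c(6, 5, 4))
  write_volume(v, file.path(d, "s"), "slice_stack")
  files <- list.files(file.path(d, "s"))
  expect_identical(files, sort(files))
  back <- read_volume(file.path(d, "s"))
  expect_equal(unclass(back)[, , 1], extract_slice(v, 1),
               tolerance = 1 / 65535)
})

test_that("inconsistent slice dimensions raise a shape error", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "bad"))
  tiff::writeTIFF(matrix(0.5, 8, 8), file.path(d, "bad", "a.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0.5, 7, 8), file.path(d, "bad", "b.tif"),
                  bits.per.sample = 16L)
  expect_error(read_volume(file.path(d, "bad")), "inconsistent slice")
})

test_that("writing under a nonexistent parent raises an I/O error", {
  v <- rand_vol(c(4, 4, 4))
  expect_error(write_volume(v, "/nonexistent_dir_xyz/v.nii.gz"),
               "parent directory")
  expect_error(read_volume("/nonexistent_dir_xyz/v.nii.gz"),
               "does not exist")
})

test_that("normalize_hu windows, clips and is idempotent on [0,1] data", {
  raw <- array(c(-1000, 2000, 500, -2000, 3000, 0), c(1, 2, 3))
  v <- normalize_hu(raw, c(-1000, 2000))
  expect_equal(as.vector(unclass(v)),
               c(0, 1, 0.5, 0, 1, 1 / 3))
  expect_error(normalize_hu(raw, c(5, 5)), "low < high")
  w <- rand_vol(c(4, 4, 4))
  expect_equal(unclass(normalize_hu(unclass(w), c(0, 1))), unclass(w))
  # monotone non-decreasing in the raw value
  r1 <- sort(runif(64, -500, 1500))
  out <- normalize_hu(array(r1, c(4, 4, 4)), c(0, 1000))
  expect_true(all(diff(as.vector(unclass(out))) >= 0))
})

test_that("extract_slice partitions a volume and stacking reassembles it", {
  withr::local_seed(3)
  v <- rand_vol(c(5, 6, 7))
  slices <- lapply(seq_len(dim(v)[3]), extract_slice, v = v)
  expect_identical(unclass(stack_slices(slices)), unclass(v))
  expect_equal(extract_slice(v, 1), unclass(v)[, , 1])
  expect_error(extract_slice(v, 0), "out of range")
  expect_error(extract_slice(v, dim(v)[3] + 1L), "out of range")
})

test_that("image sets carry z positions through disk round-trips", {
  v <- rand_vol(c(8, 8, 8))
  iset <- degrade_to_condition(v, "sparse_slices", step = 3L)
  expect_identical(iset$z_index, c(1L, 4L, 7L))
  d <- withr::local_tempdir()
  write_image_set(iset, file.path(d, "cond"))
  back <- read_image_set(file.path(d, "cond"))
  expect_identical(back$z_index, iset$z_index)
  expect_lte(max(abs(back$slices - iset$slices)), 1 / 65535)
})
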