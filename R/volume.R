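#' Volumetric intensity grids and slice stacks
#'
#' A `voxgan_volume` is a dense 3D array of voxel intensities with dimensions
#' `(l, w, h)` -- the x, y and z resolutions -- normalized to `[0, 1]`.
#' The z axis is the axial (slice) axis. Voxels enumerate in R's column-major
#' order: x fastest, then y, then z, so the m-th voxel of the flattened array
#' is the m-th voxel in raster order.
#'
#' @param data numeric 3D array of finite values in `[0, 1]`.
#' @param spacing optional numeric length-3 vector, per-axis voxel size in mm.
#' @return `as_volume()` returns a `voxgan_volume`: the array with class and
#'   optional `spacing` attribute attached.
#' @examples
#' v <- as_volume(array(runif(8 * 8 * 4), c(8, 8, 4)))
#' dim(v)
#' @export
as_volume <- function(data, spacing = NULL) {
  v <- new_volume(data, spacing)
  validate_volume(v)
  v
}

# internal constructor: no range validation (raw imports may carry HU values
# that still need normalize_hu())
new_volume <- function(data, spacing = NULL) {
  if (is.list(data) || !is.numeric(data) && !is.integer(data))
    stop("volume data must be a numeric 3D array", call. = FALSE)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 dimensions, got ",
         length(dim(data)), call. = FALSE)
  storage.mode(data) <- "double"
  structure(data, class = c("voxgan_volume", "array"), spacing = spacing)
}

#' Validate the volume contract
#'
#' Checks that every voxel is finite and in `[0, 1]` and that all three
#' dimensions are at least 1. Called by [as_volume()]; exported so pipelines
#' can re-assert the contract after arithmetic.
#'
#' @param v a `voxgan_volume` or 3D array.
#' @return `v`, invisibly.
#' @export
validate_volume <- function(v) {
  d <- dim(v)
  if (length(d) != 3L || any(d < 1L))
    stop("volume must be 3D with all dimensions >= 1", call. = FALSE)
  if (!all(is.finite(v)))
    stop("volume contains non-finite voxel values", call. = FALSE)
  r <- range(v)
  if (r[1] < 0 || r[2] > 1)
    stop(sprintf("voxel values outside [0, 1]: range [%g, %g]", r[1], r[2]),
         call. = FALSE)
  invisible(v)
}

#' @export
print.voxgan_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<voxgan_volume> %d x %d x %d voxels, range [%.4g, %.4g]%s\n",
              d[1], d[2], d[3], min(x), max(x),
              if (is.null(sp)) "" else
                sprintf(", spacing %s mm", paste(sp, collapse = " x "))))
  invisible(x)
}

#' @rdname as_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "voxgan_volume")

#' Ordered stack of conditioning slices
#'
#' An image set is the conditioning input of the volume generator: an ordered
#' stack of K grayscale xy-slices sharing one `(l, w)` resolution, values in
#' `[0, 1]`. `z_index` records which axial position (1-based) each slice
#' occupies in the volume it conditions; sparse sets leave gaps that the
#' generator zero-fills.
#'
#' @param slices 3D array `(l, w, K)` or list of K equal-sized matrices.
#' @param z_index integer vector of length K, strictly increasing axial
#'   positions; defaults to `1:K` (a full stack).
#' @return a `voxgan_image_set` (list with `slices` array and `z_index`).
#' @export
image_set <- function(slices, z_index = NULL) {
  if (is.list(slices)) {
    d <- dim(slices[[1]])
    if (is.null(d) || length(d) != 2L)
      stop("each slice must be a 2D matrix", call. = FALSE)
    if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1))))
      stop("all slices must share one resolution", call. = FALSE)
    slices <- array(unlist(slices, use.names = FALSE), c(d, length(slices)))
  }
  if (length(dim(slices)) == 2L) slices <- array(slices, c(dim(slices), 1L))
  if (length(dim(slices)) != 3L)
    stop("slices must form a 3D (l, w, K) array", call. = FALSE)
  k <- dim(slices)[3]
  if (k < 1L) stop("an image set needs at least one slice", call. = FALSE)
  if (!all(is.finite(slices)) || min(slices) < 0 || max(slices) > 1)
    stop("slice values must be finite and in [0, 1]", call. = FALSE)
  if (is.null(z_index)) z_index <- seq_len(k)
  z_index <- as.integer(z_index)
  if (length(z_index) != k || any(diff(z_index) <= 0L) || z_index[1] < 1L)
    stop("z_index must be strictly increasing positive integers, one per slice",
         call. = FALSE)
  structure(list(slices = slices, z_index = z_index),
            class = "voxgan_image_set")
}

#' @export
print.voxgan_image_set <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<voxgan_image_set> %d slice(s) of %d x %d, z positions %s\n",
              d[3], d[1], d[2],
              paste(range(x$z_index), collapse = "..")))
  invisible(x)
}

#' Extract one axial slice from a volume
#'
#' Returns the k-th xy-plane (z = k, 1-based). Stacking
#' `extract_slice(v, k)` over all k reconstitutes the volume exactly.
#'
#' @param v a `voxgan_volume` (or 3D array).
#' @param k slice index, `1 <= k <= dim(v)[3]`.
#' @return an `l x w` matrix.
#' @export
extract_slice <- function(v, k) {
  h <- dim(v)[3]
  if (length(k) != 1L || !is.finite(k) || k != as.integer(k))
    stop("slice index k must be a single integer", call. = FALSE)
  if (k < 1L || k > h)
    stop(sprintf("slice index %d out of range [1, %d]", as.integer(k), h),
         call. = FALSE)
  unclass(v)[, , k]
}

#' Reassemble a volume from axial slices
#'
#' Inverse of slicing a full stack: `stack_slices(lapply(1:h, extract_slice, v = v))`
#' reproduces `v`.
#'
#' @param slices list of equal-sized matrices, or a `voxgan_image_set`
#'   covering every z position.
#' @param spacing optional mm spacing passed to [as_volume()].
#' @return a `voxgan_volume`.
#' @export
stack_slices <- function(slices, spacing = NULL) {
  if (inherits(slices, "voxgan_image_set")) {
    if (!identical(slices$z_index, seq_len(dim(slices$slices)[3])))
      stop("image set is sparse; cannot reassemble a full volume", call. = FALSE)
    return(as_volume(slices$slices, spacing))
  }
  as_volume(image_set(slices)$slices, spacing)
}

# shared shape guard for two-volume operations
check_same_shape <- function(v, vhat) {
  if (!identical(dim(v), dim(vhat)))
    stop(sprintf("volume shapes differ: (%s) vs (%s)",
                 paste(dim(v), collapse = ","),
                 paste(dim(vhat), collapse = ",")), call. = FALSE)
  invisible(NULL)
}
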