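#' Read a volume from NIfTI or a directory of slice images
#'
#' Slice stacks are directories of equally sized grayscale images
#' (`.tif`/`.tiff`/`.png`), read in lexicographic filename order; slice 1 of
#' the stack becomes z = 1 of the volume (first NIfTI plane likewise).
#' Intensities are returned as stored: a raw CT import may carry
#' Hounsfield-like values and must go through [normalize_hu()] before use in
#' any downstream operation, all of which require `[0, 1]` volumes.
#'
#' @param path NIfTI file or slice-stack directory.
#' @param format `"auto"` (directory implies slice_stack), `"nifti"`, or
#'   `"slice_stack"`.
#' @return a `voxgan_volume` (range-unchecked if the source is raw).
#' @export
read_volume <- function(path, format = c("auto", "nifti", "slice_stack")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (dir.exists(path)) "slice_stack" else "nifti"
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")",
                                             call. = FALSE))
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim(arr)[1:3])
    pd <- tryCatch(RNifti::pixdim(img), error = function(e) NULL)
    spacing <- if (!is.null(pd) && length(pd) >= 3) pd[1:3] else NULL
    return(new_volume(arr, spacing))
  }
  if (!dir.exists(path))
    stop("slice_stack path must be a directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no .tif/.tiff/.png slices found in ", path, call. = FALSE)
  slices <- lapply(files, read_slice_image)
  d <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), d), logical(1))
  if (!all(ok))
    stop(sprintf("inconsistent slice dimensions: '%s' is %s but '%s' is %s",
                 basename(files[1]), paste(d, collapse = "x"),
                 basename(files[which(!ok)[1]]),
                 paste(dim(slices[[which(!ok)[1]]]), collapse = "x")),
         call. = FALSE)
  new_volume(array(unlist(slices, use.names = FALSE), c(d, length(slices))))
}

read_slice_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(f) else png::readPNG(f)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # grayscale channel
  img
}

#' Write a volume to NIfTI or a 16-bit TIFF slice stack
#'
#' NIfTI output stores double precision, so `read_volume(write_volume(v))`
#' is value-exact. Slice stacks store 16-bit grayscale TIFF, one file per
#' axial slice (`slice_0001.tif`, ...), so round-trips are exact to the
#' 16-bit quantization step 1/65535.
#'
#' @param v a `voxgan_volume` with values in `[0, 1]`.
#' @param path target file (nifti) or directory (slice_stack; created if
#'   missing, but its parent must exist).
#' @param format `"nifti"` or `"slice_stack"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("nifti", "slice_stack")) {
  format <- match.arg(format)
  parent <- dirname(path)
  if (!dir.exists(parent))
    stop("parent directory does not exist: ", parent, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::asNifti(unclass(v), datatype = "double")
    sp <- attr(v, "spacing")
    if (!is.null(sp)) RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    if (!dir.exists(path)) dir.create(path)
    h <- dim(v)[3]
    for (k in seq_len(h))
      tiff::writeTIFF(extract_slice(v, k),
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write / read a conditioning image set as a slice-stack directory
#'
#' Slices are stored as 16-bit grayscale TIFF named `slice_z<k>.tif` where
#' `<k>` is the axial position the slice occupies, so sparse image sets
#' round-trip with their z positions intact.
#'
#' @param iset a `voxgan_image_set`.
#' @param path directory (created if missing; parent must exist).
#' @return `path` / the restored `voxgan_image_set`.
#' @export
write_image_set <- function(iset, path) {
  if (!inherits(iset, "voxgan_image_set"))
    stop("iset must be a voxgan_image_set", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  if (!dir.exists(path)) dir.create(path)
  for (i in seq_along(iset$z_index))
    tiff::writeTIFF(iset$slices[, , i],
                    file.path(path, sprintf("slice_z%04d.tif",
                                            iset$z_index[i])),
                    bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path) {
  files <- sort(list.files(path, pattern = "^slice_z\\d+\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no slice_z*.tif slices found in ", path, call. = FALSE)
  z <- as.integer(sub("^slice_z(\\d+)\\..*$", "\\1", basename(files)))
  o <- order(z)
  slices <- lapply(files[o], read_slice_image)
  image_set(slices, z_index = z[o])
}

#' Window-normalize Hounsfield-like intensities to [0, 1]
#'
#' Applies the linear window map `clip((raw - low) / (high - low), 0, 1)`,
#' monotone non-decreasing in the raw value. The default window
#' (-1000, 2000) HU spans air to dense bone; already-normalized data pass
#' through unchanged under window `(0, 1)`.
#'
#' @param raw 3D array (or volume) of raw intensities.
#' @param window numeric `(low, high)` with `low < high`.
#' @param spacing optional mm spacing for the returned volume.
#' @return a `voxgan_volume` in `[0, 1]`.
#' @export
normalize_hu <- function(raw, window = c(-1000, 2000), spacing = NULL) {
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be (low, high) with low < high", call. = FALSE)
  if (is.null(spacing)) spacing <- attr(raw, "spacing")
  x <- (unclass(raw) - window[1]) / (window[2] - window[1])
  as_volume(array(pmin(pmax(x, 0), 1), dim(raw)), spacing)
}
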