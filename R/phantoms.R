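#' Specify a synthetic anatomical phantom
#'
#' Phantoms emulate the intensity structure the reconstruction method
#' assumes of normalized CT: a low-value background majority (the undefined
#' region outside the anatomy), a mid-value interior, and -- for bone-like
#' kinds -- a thin high-value cortical shell whose voxels dominate the upper
#' quartile of the intensity distribution.
#'
#' Kinds:
#' * `vertebra` -- ellipsoidal body with a ~2-voxel high-intensity cortical
#'   shell plus a posterior rectangular process (rigid-structure regime,
#'   thresholded at Q3 downstream);
#' * `liver` -- smooth-edged union of two overlapping ellipsoids at interior
#'   intensity, no shell (soft-tissue regime, Q1 thresholds);
#' * `sphere` -- solid ball with a thin shell, the simplest bone-like case.
#'
#' @param kind one of `"vertebra"`, `"liver"`, `"sphere"`.
#' @param resolution integer `(l, w, h)`, each >= 8; a scalar is recycled.
#' @param shell_intensity,interior_intensity,background_intensity intensities
#'   in `[0, 1]`; bone-like kinds require background < interior < shell.
#' @param noise_sd sd of additive Gaussian noise (added before clipping to
#'   `[0, 1]`).
#' @param deform magnitude of the random affine jitter (per-axis scale and
#'   rotation drawn uniformly in `+/- deform`, translation in
#'   `+/- deform / 2`, in normalized coordinates).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return a `voxgan_phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("vertebra", "liver", "sphere"),
                         resolution = c(32L, 32L, 32L),
                         shell_intensity = 0.9,
                         interior_intensity = 0.55,
                         background_intensity = 0.08,
                         noise_sd = 0.02,
                         deform = 0.05,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (length(resolution) == 1L) resolution <- rep(resolution, 3L)
  resolution <- as.integer(resolution)
  if (length(resolution) != 3L || any(resolution < 8L))
    stop("resolution must be three integers, each >= 8", call. = FALSE)
  for (v in c(shell_intensity, interior_intensity, background_intensity))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("intensities must lie in [0, 1]", call. = FALSE)
  if (kind %in% c("vertebra", "sphere") &&
      !(background_intensity < interior_intensity &&
        interior_intensity < shell_intensity))
    stop("bone-like phantoms require background < interior < shell intensity",
         call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.finite(deform) || deform < 0)
    stop("deform must be >= 0", call. = FALSE)
  structure(list(kind = kind, resolution = resolution,
                 shell_intensity = shell_intensity,
                 interior_intensity = interior_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, deform = deform,
                 seed = as.integer(seed)),
            class = "voxgan_phantom_spec")
}

#' Generate one phantom pair (ground truth + conditioning image set)
#'
#' Deterministic given `spec` (including its seed): the RNG is seeded
#' locally and restored afterwards. The conditioning image set is derived
#' from the truth via [degrade_to_condition()].
#'
#' @param spec a [phantom_spec()].
#' @param condition_mode,condition_params forwarded to
#'   [degrade_to_condition()].
#' @return a `voxgan_phantom_pair`: list with `truth` (volume), `condition`
#'   (image set) and `spec`.
#' @export
make_phantom <- function(spec, condition_mode = "full_stack",
                         condition_params = list()) {
  if (!inherits(spec, "voxgan_phantom_spec"))
    stop("spec must come from phantom_spec()", call. = FALSE)
  truth <- with_local_seed(spec$seed, phantom_geometry(spec))
  condition <- do.call(degrade_to_condition,
                       c(list(truth = truth, mode = condition_mode,
                              seed = spec$seed + 1L),
                         condition_params))
  structure(list(truth = truth, condition = condition, spec = spec),
            class = "voxgan_phantom_pair")
}

# evaluate the phantom's implicit geometry on the (deformed) unit cube grid;
# assumes the RNG is already seeded
phantom_geometry <- function(spec) {
  res <- spec$resolution
  l <- res[1]; w <- res[2]; h <- res[3]
  # random affine jitter of the sampling frame
  scl <- 1 + runif(3, -spec$deform, spec$deform)
  ang <- runif(3, -spec$deform, spec$deform)
  trn <- runif(3, -spec$deform / 2, spec$deform / 2)
  cx <- seq(-1, 1, length.out = l)
  cy <- seq(-1, 1, length.out = w)
  cz <- seq(-1, 1, length.out = h)
  g <- expand.grid(x = cx, y = cy, z = cz)  # x fastest: raster order
  p <- cbind(g$x, g$y, g$z)
  rot <- rot3(ang)
  p <- (p %*% t(rot)) * rep(scl, each = nrow(p)) +
    rep(trn, each = nrow(p))
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  bg <- spec$background_intensity
  mid <- spec$interior_intensity
  top <- spec$shell_intensity
  vals <- rep(bg, nrow(p))
  thick <- 2 * (2 / min(res))  # ~2 voxels in normalized coordinates
  if (spec$kind == "sphere") {
    r <- sqrt(x^2 + y^2 + z^2)
    r0 <- 0.75
    vals[r <= r0] <- mid
    vals[r <= r0 & r > r0 - thick] <- top
  } else if (spec$kind == "vertebra") {
    # vertebral body: large ellipsoid; radial coordinate of its surface
    e <- sqrt((x / 0.95)^2 + (y / 0.80)^2 + (z / 0.72)^2)
    vals[e <= 1] <- mid + 0.06 * (1 - e[e <= 1]^2)  # faint density gradient
    vals[e <= 1 & e > 1 - thick / 0.8] <- top
    # posterior process: rectangular bar at cortical intensity
    proc <- abs(x) <= 0.18 & y <= -0.55 & y >= -0.98 & abs(z) <= 0.45
    vals[proc] <- top
  } else {  # liver: two soft-edged overlapping ellipsoids, no shell
    e1 <- sqrt((x / 0.85)^2 + ((y - 0.15) / 0.70)^2 + (z / 0.60)^2)
    e2 <- sqrt(((x - 0.25) / 0.60)^2 + ((y + 0.35) / 0.55)^2 +
                 ((z - 0.10) / 0.50)^2)
    e <- pmin(e1, e2)
    edge <- 0.12  # soft boundary width in normalized units
    s <- pmin(pmax((1 - e) / edge, 0), 1)
    s <- s * s * (3 - 2 * s)  # smoothstep
    vals <- bg + (mid - bg) * s
  }
  if (spec$noise_sd > 0)
    vals <- vals + rnorm(length(vals), 0, spec$noise_sd)
  as_volume(array(pmin(pmax(vals, 0), 1), res))
}

rot3 <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' Degrade a ground-truth volume into a conditioning image set
#'
#' @param truth a `voxgan_volume`.
#' @param mode `"full_stack"` (every axial slice, unchanged),
#'   `"sparse_slices"` (every `step`-th slice), or `"noisy_stack"` (every
#'   slice plus clipped Gaussian noise).
#' @param step slice stride for `sparse_slices`; must not exceed the number
#'   of slices.
#' @param noise_sd per-slice noise sd for `noisy_stack`.
#' @param seed optional seed making the degradation reproducible.
#' @return a `voxgan_image_set` with values in `[0, 1]`.
#' @export
degrade_to_condition <- function(truth,
                                 mode = c("full_stack", "sparse_slices",
                                          "noisy_stack"),
                                 step = 4L, noise_sd = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  validate_volume(truth)
  h <- dim(truth)[3]
  if (mode == "sparse_slices") {
    step <- as.integer(step)
    if (step < 1L || step > h)
      stop(sprintf("sparse step %d outside [1, %d]", step, h), call. = FALSE)
    z <- seq(1L, h, by = step)
  } else {
    z <- seq_len(h)
  }
  slices <- unclass(truth)[, , z, drop = FALSE]
  if (mode == "noisy_stack" && noise_sd > 0) {
    noise_fn <- function() {
      slices + array(rnorm(length(slices), 0, noise_sd), dim(slices))
    }
    slices <- if (is.null(seed)) noise_fn() else with_local_seed(seed, noise_fn())
    slices <- pmin(pmax(slices, 0), 1)
  }
  image_set(array(slices, c(dim(truth)[1:2], length(z))), z_index = z)
}

#' Generate a reproducible dataset of phantom pairs
#'
#' Item seeds derive from the master seed by a counter-based splitting
#' scheme, so item i is identical no matter how many items are generated or
#' in what order.
#'
#' @param n number of pairs, >= 1.
#' @param spec_template a [phantom_spec()] whose seed field is ignored.
#' @param seed master seed.
#' @param condition_mode,condition_params forwarded to [make_phantom()].
#' @return list of `n` `voxgan_phantom_pair`s.
#' @export
make_dataset <- function(n, spec_template, seed = 1L,
                         condition_mode = "full_stack",
                         condition_params = list()) {
  if (length(n) != 1L || !is.finite(n) || n < 1L)
    stop("n must be a positive integer", call. = FALSE)
  if (!inherits(spec_template, "voxgan_phantom_spec"))
    stop("spec_template must come from phantom_spec()", call. = FALSE)
  lapply(seq_len(n), function(i) {
    s <- spec_template
    s$seed <- item_seed(seed, i)
    make_phantom(s, condition_mode, condition_params)
  })
}

# counter-based seed split: stays below 2^31 - 1
item_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + i * 7919) %% 2147483629)
}

# run code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
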