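#' Configure the conditional volume generator
#'
#' The generator maps a conditioning image set to a volume through four
#' stages: a multi-scale local feature fusion block (LFFB: a 3x3x3 stem,
#' parallel 3D convs at the configured kernel sizes, channel concatenation,
#' 1x1x1 fusion, and a local residual onto the stem), a strided 4^3-conv
#' encoder, a stack of ResNet-style refiner blocks with dropout at the
#' bottleneck, a transposed-conv decoder with U-Net skip connections, and a
#' resolution-preserving 4^3 output conv squashed to `[0, 1]` by a sigmoid.
#'
#' @param depth_down encoder layers (= decoder layers; each halves/doubles
#'   resolution).
#' @param depth_mid refiner residual blocks at the bottleneck.
#' @param base_channels channel width after the LFFB.
#' @param channel_growth per-level channel multiplier.
#' @param channel_cap maximum channel width.
#' @param dropout dropout rate inside refiner blocks, `[0, 1)`.
#' @param lffb_branches odd kernel sizes of the LFFB's parallel branches.
#' @param out_resolution `(l, w, h)`, each divisible by `2^depth_down`.
#' @return a `voxgan_generator_config`.
#' @export
generator_config <- function(depth_down = 3L, depth_mid = 3L,
                             base_channels = 16L, channel_growth = 2,
                             channel_cap = 256L, dropout = 0.2,
                             lffb_branches = c(1L, 3L, 5L),
                             out_resolution = c(16L, 16L, 16L)) {
  if (length(out_resolution) == 1L) out_resolution <- rep(out_resolution, 3L)
  out_resolution <- as.integer(out_resolution)
  depth_down <- as.integer(depth_down)
  if (depth_down < 1L || depth_mid < 0L)
    stop("depth_down must be >= 1 and depth_mid >= 0", call. = FALSE)
  if (any(out_resolution %% 2L^depth_down != 0L))
    stop(sprintf("out_resolution (%s) must be divisible by 2^depth_down = %d",
                 paste(out_resolution, collapse = "x"), 2L^depth_down),
         call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (any(lffb_branches %% 2L == 0L))
    stop("lffb_branches must be odd kernel sizes", call. = FALSE)
  structure(list(depth_down = depth_down, depth_mid = as.integer(depth_mid),
                 depth_up = depth_down,
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 channel_cap = as.integer(channel_cap),
                 dropout = dropout,
                 lffb_branches = as.integer(lffb_branches),
                 out_resolution = out_resolution),
            class = "voxgan_generator_config")
}

#' Configure the volumetric discriminator
#'
#' A stack of 4^3 stride-2 convolutions over the channel-wise combination
#' of conditioning and candidate volume, followed by a fully connected
#' layer with sigmoid producing an authenticity score in `(0, 1)`.
#'
#' @param depth number of strided conv layers.
#' @param base_channels,channel_growth,channel_cap as in
#'   [generator_config()].
#' @param in_resolution `(l, w, h)` of candidate volumes, divisible by
#'   `2^depth`.
#' @return a `voxgan_discriminator_config`.
#' @export
discriminator_config <- function(depth = 3L, base_channels = 16L,
                                 channel_growth = 2, channel_cap = 256L,
                                 in_resolution = c(16L, 16L, 16L)) {
  if (length(in_resolution) == 1L) in_resolution <- rep(in_resolution, 3L)
  in_resolution <- as.integer(in_resolution)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (any(in_resolution %% 2L^depth != 0L) ||
      any(in_resolution %/% 2L^depth < 1L))
    stop(sprintf(
      "in_resolution (%s) must be divisible by 2^depth = %d with extent >= 1",
      paste(in_resolution, collapse = "x"), 2L^depth), call. = FALSE)
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 channel_cap = as.integer(channel_cap),
                 in_resolution = in_resolution),
            class = "voxgan_discriminator_config")
}

gen_channels <- function(cfg)
  as.integer(pmin(cfg$base_channels * cfg$channel_growth^(0:cfg$depth_down),
                  cfg$channel_cap))

disc_channels <- function(cfg)
  as.integer(pmin(cfg$base_channels * cfg$channel_growth^(0:(cfg$depth - 1L)),
                  cfg$channel_cap))

init_conv_w <- function(k, cin, cout, sd = 0.02)
  matrix(rnorm(k^3 * cin * cout, 0, sd), k^3 * cin, cout)

#' Build a generator with deterministic parameter initialization
#'
#' Weights are drawn `N(0, 0.02)` under the given seed (same seed, same
#' parameters, bit for bit); instance-norm gains start at 1, all biases and
#' shifts at 0.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed for the parameter draw.
#' @return a `voxgan_generator`: list with `cfg`, named `params`, `seed`.
#' @export
build_generator <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "voxgan_generator_config"))
  ch <- gen_channels(cfg)
  c0 <- ch[1]
  P <- list()
  with_local_seed(seed, {
    P$lffb_stem_w <- init_conv_w(3L, 1L, c0)
    P$lffb_stem_b <- numeric(c0)
    for (i in seq_along(cfg$lffb_branches)) {
      k <- cfg$lffb_branches[i]
      P[[sprintf("lffb_branch%d_w", i)]] <- init_conv_w(k, c0, c0)
      P[[sprintf("lffb_branch%d_b", i)]] <- numeric(c0)
    }
    P$lffb_fuse_w <- init_conv_w(1L, c0 * length(cfg$lffb_branches), c0)
    P$lffb_fuse_b <- numeric(c0)
    for (d in seq_len(cfg$depth_down)) {
      P[[sprintf("down%d_w", d)]] <- init_conv_w(4L, ch[d], ch[d + 1])
      P[[sprintf("down%d_b", d)]] <- numeric(ch[d + 1])
      if (d > 1L) {
        P[[sprintf("down%d_gamma", d)]] <- rep(1, ch[d + 1])
        P[[sprintf("down%d_beta", d)]] <- numeric(ch[d + 1])
      }
    }
    cm <- ch[cfg$depth_down + 1]
    for (r in seq_len(cfg$depth_mid)) {
      for (j in 1:2) {
        P[[sprintf("mid%d_conv%d_w", r, j)]] <- init_conv_w(4L, cm, cm)
        P[[sprintf("mid%d_conv%d_b", r, j)]] <- numeric(cm)
        P[[sprintf("mid%d_in%d_gamma", r, j)]] <- rep(1, cm)
        P[[sprintf("mid%d_in%d_beta", r, j)]] <- numeric(cm)
      }
    }
    for (u in seq_len(cfg$depth_down)) {
      lev <- cfg$depth_down - u + 1L        # resolution level being left
      cin <- if (u == 1L) ch[cfg$depth_down + 1] else 2L * ch[lev + 1]
      cout <- ch[lev]
      P[[sprintf("up%d_w", u)]] <- init_conv_w(4L, cout, cin)  # adjoint layout
      P[[sprintf("up%d_b", u)]] <- numeric(cout)
      P[[sprintf("up%d_gamma", u)]] <- rep(1, cout)
      P[[sprintf("up%d_beta", u)]] <- numeric(cout)
    }
    P$out_w <- init_conv_w(4L, 2L * c0, 1L)
    P$out_b <- numeric(1L)
  })
  structure(list(cfg = cfg, params = P, seed = as.integer(seed)),
            class = "voxgan_generator")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "voxgan_discriminator_config"))
  ch <- disc_channels(cfg)
  P <- list()
  with_local_seed(seed, {
    for (k in seq_len(cfg$depth)) {
      cin <- if (k == 1L) 2L else ch[k - 1]
      P[[sprintf("d%d_w", k)]] <- init_conv_w(4L, cin, ch[k])
      P[[sprintf("d%d_b", k)]] <- numeric(ch[k])
      if (k > 1L) {
        P[[sprintf("d%d_gamma", k)]] <- rep(1, ch[k])
        P[[sprintf("d%d_beta", k)]] <- numeric(ch[k])
      }
    }
    ext <- cfg$in_resolution %/% 2L^cfg$depth
    nin <- prod(ext) * ch[cfg$depth]
    P$fc_w <- matrix(rnorm(nin, 0, 0.02), 1L, nin)
    P$fc_b <- 0
  })
  structure(list(cfg = cfg, params = P, seed = as.integer(seed)),
            class = "voxgan_discriminator")
}

# embed an image set into a 1-channel 3D tensor on the output grid; sparse
# sets leave zeros at missing z positions
condition_tensor <- function(image_set, out_resolution) {
  if (!inherits(image_set, "voxgan_image_set"))
    stop("condition must be a voxgan_image_set", call. = FALSE)
  d <- dim(image_set$slices)
  if (d[1] != out_resolution[1] || d[2] != out_resolution[2])
    stop(sprintf("slice resolution %dx%d does not match volume %dx%d",
                 d[1], d[2], out_resolution[1], out_resolution[2]),
         call. = FALSE)
  if (max(image_set$z_index) > out_resolution[3])
    stop("image set z positions exceed the volume's z extent", call. = FALSE)
  arr <- array(0, c(out_resolution, 1L))
  arr[, , image_set$z_index, 1] <- image_set$slices
  arr
}

# generator forward on a tape; P entries may be ad nodes (training) or
# plain arrays (inference). Returns the pre-class volume node.
gen_forward_node <- function(tape, P, cfg, cond, train = FALSE,
                             shapes = NULL) {
  res <- cfg$out_resolution
  ch <- gen_channels(cfg)
  note <- function(name, nd) {
    if (!is.null(shapes)) shapes[[name]] <- dim(ad_val(nd))
    nd
  }
  stem <- ad_leaky_relu(tape, ad_conv3d(tape, cond, P$lffb_stem_w,
                                        P$lffb_stem_b, 3L, 1L, c(1L, 1L)))
  note("lffb_stem", stem)
  branches <- lapply(seq_along(cfg$lffb_branches), function(i) {
    k <- cfg$lffb_branches[i]
    ad_leaky_relu(tape, ad_conv3d(tape, stem,
                                  P[[sprintf("lffb_branch%d_w", i)]],
                                  P[[sprintf("lffb_branch%d_b", i)]],
                                  k, 1L, c((k - 1L) %/% 2L, (k - 1L) %/% 2L)))
  })
  fused <- ad_conv3d(tape, ad_concat_ch(tape, branches),
                     P$lffb_fuse_w, P$lffb_fuse_b, 1L, 1L, c(0L, 0L))
  lffb <- note("lffb", ad_add(tape, fused, stem))
  enc <- vector("list", cfg$depth_down)
  x <- lffb
  for (d in seq_len(cfg$depth_down)) {
    x <- ad_conv3d(tape, x, P[[sprintf("down%d_w", d)]],
                   P[[sprintf("down%d_b", d)]], 4L, 2L, c(1L, 1L))
    if (d > 1L)
      x <- ad_instnorm(tape, x, P[[sprintf("down%d_gamma", d)]],
                       P[[sprintf("down%d_beta", d)]])
    x <- ad_leaky_relu(tape, x)
    enc[[d]] <- note(sprintf("down%d", d), x)
  }
  for (r in seq_len(cfg$depth_mid)) {
    h1 <- ad_relu(tape, ad_instnorm(tape,
      ad_conv3d(tape, x, P[[sprintf("mid%d_conv1_w", r)]],
                P[[sprintf("mid%d_conv1_b", r)]], 4L, 1L, c(1L, 2L)),
      P[[sprintf("mid%d_in1_gamma", r)]], P[[sprintf("mid%d_in1_beta", r)]]))
    h1 <- ad_dropout(tape, h1, cfg$dropout, train)
    h2 <- ad_instnorm(tape,
      ad_conv3d(tape, h1, P[[sprintf("mid%d_conv2_w", r)]],
                P[[sprintf("mid%d_conv2_b", r)]], 4L, 1L, c(1L, 2L)),
      P[[sprintf("mid%d_in2_gamma", r)]], P[[sprintf("mid%d_in2_beta", r)]])
    x <- note(sprintf("mid%d", r), ad_add(tape, x, h2))
  }
  for (u in seq_len(cfg$depth_down)) {
    lev <- cfg$depth_down - u + 1L
    out_sp <- res %/% 2L^(lev - 1L)
    x <- ad_convt3d(tape, x, P[[sprintf("up%d_w", u)]],
                    P[[sprintf("up%d_b", u)]], 4L, 2L, c(1L, 1L), out_sp)
    x <- ad_relu(tape, ad_instnorm(tape, x, P[[sprintf("up%d_gamma", u)]],
                                   P[[sprintf("up%d_beta", u)]]))
    skip <- if (lev - 1L >= 1L) enc[[lev - 1L]] else lffb
    x <- note(sprintf("up%d", u), ad_concat_ch(tape, list(x, skip)))
  }
  note("out", ad_sigmoid(tape, ad_conv3d(tape, x, P$out_w, P$out_b,
                                         4L, 1L, c(1L, 2L))))
}

# vol may be an ad node (gradient flows into the generator), a plain
# (l, w, h, 1) array, or a bare 3D volume
disc_forward_node <- function(tape, P, cfg, cond, vol) {
  if (!is_ad_node(vol) && length(dim(vol)) == 3L)
    vol <- array(unclass(vol), c(dim(vol), 1L))
  x <- ad_concat_ch(tape, list(cond, vol))
  for (k in seq_len(cfg$depth)) {
    x <- ad_conv3d(tape, x, P[[sprintf("d%d_w", k)]],
                   P[[sprintf("d%d_b", k)]], 4L, 2L, c(1L, 1L))
    if (k > 1L)
      x <- ad_instnorm(tape, x, P[[sprintf("d%d_gamma", k)]],
                       P[[sprintf("d%d_beta", k)]])
    x <- ad_leaky_relu(tape, x)
  }
  ad_sigmoid(tape, ad_linear(tape, x, P$fc_w, P$fc_b))
}

#' Run the generator / discriminator forward
#'
#' `generator_forward` maps a conditioning image set to a volume
#' (evaluation mode by default: dropout off, so repeated calls are
#' bit-identical). `discriminator_forward` scores a (condition, volume)
#' pair with an authenticity probability in `(0, 1)`.
#'
#' @param G,D networks from [build_generator()] / [build_discriminator()].
#' @param image_set conditioning `voxgan_image_set` on the network's grid.
#' @param train logical; enables dropout (draws from the global RNG).
#' @param return_shapes also return the measured intermediate layer shapes.
#' @return `generator_forward`: a `voxgan_volume` (with attribute `shapes`
#'   if requested); `discriminator_forward`: a scalar in `(0, 1)`.
#' @export
generator_forward <- function(G, image_set, train = FALSE,
                              return_shapes = FALSE) {
  stopifnot(inherits(G, "voxgan_generator"))
  cond <- condition_tensor(image_set, G$cfg$out_resolution)
  tape <- ad_tape()
  shapes <- if (return_shapes) new.env() else NULL
  out <- gen_forward_node(tape, G$params, G$cfg, cond, train, shapes)
  v <- as_volume(array(ad_val(out), G$cfg$out_resolution))
  if (return_shapes)
    attr(v, "shapes") <- as.list(shapes)
  v
}

#' @rdname generator_forward
#' @param volume candidate `voxgan_volume` at the discriminator's
#'   `in_resolution`.
#' @export
discriminator_forward <- function(D, image_set, volume) {
  stopifnot(inherits(D, "voxgan_discriminator"))
  check_same_shape(array(0, D$cfg$in_resolution), volume)
  cond <- condition_tensor(image_set, D$cfg$in_resolution)
  tape <- ad_tape()
  ad_val(disc_forward_node(tape, D$params, D$cfg, cond, volume))
}

#' Announced layer shapes of a generator config
#'
#' Computes, by stride arithmetic alone, the spatial extent and channel
#' width after each layer group; tests compare these against the shapes
#' measured while walking the network.
#'
#' @param cfg a [generator_config()].
#' @return named list of `(l, w, h, channels)` vectors.
#' @export
generator_shapes <- function(cfg) {
  res <- cfg$out_resolution
  halved <- function(d) as.integer(res %/% 2^d)
  ch <- gen_channels(cfg)
  out <- list(lffb_stem = c(res, ch[1]), lffb = c(res, ch[1]))
  for (d in seq_len(cfg$depth_down))
    out[[sprintf("down%d", d)]] <- c(halved(d), ch[d + 1])
  for (r in seq_len(cfg$depth_mid))
    out[[sprintf("mid%d", r)]] <- c(halved(cfg$depth_down),
                                    ch[cfg$depth_down + 1])
  for (u in seq_len(cfg$depth_down)) {
    lev <- cfg$depth_down - u + 1L
    out[[sprintf("up%d", u)]] <- c(halved(lev - 1L), 2L * ch[lev])
  }
  out$out <- c(res, 1L)
  out
}
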