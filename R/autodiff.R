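# Reverse-mode automatic differentiation on dense R arrays.
#
# The networks in this package are small 3D conv nets trained on CPU; their
# forward passes are built eagerly on a tape of nodes, each recording its
# parent nodes and a backward closure. Creation order is a topological
# order, so backpropagation is a single reverse sweep. Convolutions are
# im2col gathers (index matrices cached per signature) followed by BLAS
# matrix multiplies; transposed convolutions reuse the same indices as
# scatter-adds, making them exact adjoints of the matching strided convs.
#
# Tensor layout: spatial-first arrays dim (l, w, h, C); conv weights are
# flat matrices (k^3 * C_in, C_out) whose row order matches the im2col
# patch order (dx fastest, then dy, dz, then input channel).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, value)

is_ad_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$value else x

# reverse sweep from a scalar root; leaves end up with $grad set
ad_backward <- function(tape, root) {
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g) || !is.environment(ps[[j]])) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

## ---- elementwise ops (equal shapes; constants may be plain arrays) ----

ad_add <- function(t, a, b)
  ad_node(t, ad_val(a) + ad_val(b), list(a, b),
          function(g) list(g, g))

ad_sub <- function(t, a, b)
  ad_node(t, ad_val(a) - ad_val(b), list(a, b),
          function(g) list(g, -g))

ad_mul <- function(t, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(t, va * vb, list(a, b),
          function(g) list(g * vb, g * va))
}

ad_div <- function(t, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(t, va / vb, list(a, b),
          function(g) list(g / vb, -g * va / (vb * vb)))
}

# affine map with constant scalars: k * a + c
ad_affine <- function(t, a, k = 1, c = 0)
  ad_node(t, k * ad_val(a) + c, list(a), function(g) list(k * g))

ad_abs <- function(t, a) {
  va <- ad_val(a)
  ad_node(t, abs(va), list(a), function(g) list(g * sign(va)))
}

ad_sigmoid <- function(t, a) {
  s <- plogis(ad_val(a))
  ad_node(t, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(t, a) {
  va <- ad_val(a)
  m <- va > 0
  ad_node(t, va * m, list(a), function(g) list(g * m))
}

ad_leaky_relu <- function(t, a, slope = 0.2) {
  va <- ad_val(a)
  m <- ifelse(va > 0, 1, slope)
  ad_node(t, va * m, list(a), function(g) list(g * m))
}

ad_dropout <- function(t, a, rate, train = TRUE) {
  if (!train || rate <= 0) return(a)
  va <- ad_val(a)
  keep <- array(runif(length(va)) >= rate, dim(va)) / (1 - rate)
  ad_node(t, va * keep, list(a), function(g) list(g * keep))
}

ad_mean <- function(t, a) {
  va <- ad_val(a)
  n <- length(va)
  d <- dim(va)
  ad_node(t, mean(va), list(a),
          function(g) list(array(g / n, if (is.null(d)) n else d)))
}

ad_sum <- function(t, a) {
  va <- ad_val(a)
  d <- dim(va)
  ad_node(t, sum(va), list(a),
          function(g) list(array(g, if (is.null(d)) length(va) else d)))
}

# concatenate along the channel (4th) dimension
ad_concat_ch <- function(t, xs) {
  vals <- lapply(xs, ad_val)
  chs <- vapply(vals, function(v) dim(v)[4], integer(1))
  value <- array(0, c(dim(vals[[1]])[1:3], sum(chs)))
  at <- 0L
  for (i in seq_along(vals)) {
    value[, , , at + seq_len(chs[i])] <- vals[[i]]
    at <- at + chs[i]
  }
  ad_node(t, value, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , , at + seq_len(chs[i]), drop = FALSE]
      at <- at + chs[i]
    }
    out
  })
}

## ---- convolution machinery ----

.voxgan_idx_cache <- new.env(parent = emptyenv())

# zero-pad the three spatial dims of (l, w, h, C) by pb before / pa after
# (each a scalar or per-axis length-3 vector)
pad3 <- function(x, pb, pa) {
  if (all(pb == 0) && all(pa == 0)) return(x)
  if (length(pb) == 1L) pb <- rep(pb, 3L)
  if (length(pa) == 1L) pa <- rep(pa, 3L)
  d <- dim(x)
  out <- array(0, c(d[1:3] + pb + pa, d[4]))
  out[pb[1] + seq_len(d[1]), pb[2] + seq_len(d[2]), pb[3] + seq_len(d[3]), ] <- x
  out
}

crop3 <- function(x, pb, pa) {
  if (all(pb == 0) && all(pa == 0)) return(x)
  if (length(pb) == 1L) pb <- rep(pb, 3L)
  if (length(pa) == 1L) pa <- rep(pa, 3L)
  d <- dim(x)
  x[pb[1] + seq_len(d[1] - pb[1] - pa[1]),
    pb[2] + seq_len(d[2] - pb[2] - pa[2]),
    pb[3] + seq_len(d[3] - pb[3] - pa[3]), , drop = FALSE]
}

# im2col gather indices over a padded grid (pdims, channels cin), stored
# flat: entry p*n + m maps output position m (x fastest) and patch offset p
# (dx fastest, then dy, dz, then channel) to a padded-array element.
# k may be a scalar (cubic kernel) or per-axis length-3 vector. Scatter
# grouping for the adjoint is derived lazily on first use.
conv_index <- function(pdims, k, stride, cin) {
  if (length(k) == 1L) k <- rep(k, 3L)
  key <- paste(c(pdims, k, stride, cin), collapse = "_")
  hit <- .voxgan_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  lp <- pdims[1]; wp <- pdims[2]; hp <- pdims[3]
  odims <- (pdims - k) %/% stride + 1L
  sx <- (seq_len(odims[1]) - 1L) * stride
  sy <- (seq_len(odims[2]) - 1L) * stride
  sz <- (seq_len(odims[3]) - 1L) * stride
  base <- as.vector(outer(outer(sx, lp * sy, "+"), lp * wp * sz, "+"))
  dx <- 0:(k[1] - 1); dy <- 0:(k[2] - 1); dz <- 0:(k[3] - 1)
  ch <- 0:(cin - 1)
  off <- as.vector(outer(outer(outer(dx, lp * dy, "+"), lp * wp * dz, "+"),
                         lp * wp * hp * ch, "+"))
  idx <- as.vector(outer(base, off, "+")) + 1
  storage.mode(idx) <- "integer"
  entry <- new.env(parent = emptyenv())
  entry$idx <- idx
  entry$n <- length(base)
  entry$p <- length(off)
  entry$odims <- odims
  entry$nvox <- prod(pdims) * cin
  .voxgan_idx_cache[[key]] <- entry
  entry
}

col_gather <- function(x, ci) {
  y <- x[ci$idx]
  dim(y) <- c(ci$n, ci$p)
  y
}

# scatter-add of a column matrix back onto the padded grid
col_scatter <- function(colmat, ci, cdims) {
  if (is.null(ci$uidx)) {
    ci$uidx <- sort.int(unique(ci$idx))
    ci$gmatch <- match(ci$idx, ci$uidx)
  }
  acc <- rowsum(as.vector(colmat), ci$gmatch, reorder = TRUE)
  out <- numeric(ci$nvox)
  out[ci$uidx] <- acc
  array(out, cdims)
}

# rearrange a conv weight (prod(k)*cin, cout) into the weight of the
# adjoint stride-1 gather-convolution: 180-degree kernel flip with input
# and output channels swapped -> (prod(k)*cout, cin)
flip_weight <- function(w, k, cin, cout) {
  if (length(k) == 1L) k <- rep(k, 3L)
  a <- array(w, c(k, cin, cout))
  a <- a[k[1]:1, k[2]:1, k[3]:1, , , drop = FALSE]
  a <- aperm(a, c(1:3, 5, 4))
  matrix(a, prod(k) * cout, cin)
}

# 3D convolution, kernel k (scalar or per-axis), stride s, spatial padding
# (pb, pa) on every axis. w: flat (prod(k) * cin, cout) matrix node/array;
# b: length-cout vector. For stride 1 the input gradient is computed as a
# gather-convolution with the 180-degree-flipped kernel (fast); strided
# convs fall back to the generic scatter-add adjoint.
ad_conv3d <- function(t, x, w, b, k, stride, pad) {
  vx <- ad_val(x); vw <- ad_val(w); vb <- ad_val(b)
  pb <- pad[1]; pa <- if (length(pad) > 1) pad[2] else pad[1]
  cin <- dim(vx)[4]
  cout <- ncol(vw)
  kv <- if (length(k) == 1L) rep(k, 3L) else k
  xp <- pad3(vx, pb, pa)
  ci <- conv_index(dim(xp)[1:3], k, stride, cin)
  n <- ci$n
  col <- col_gather(xp, ci)
  outm <- col %*% vw
  if (!is.null(vb)) outm <- outm + rep(vb, each = n)
  dim(outm) <- c(ci$odims, cout)
  value <- outm
  pdims <- dim(xp)
  in_sp <- dim(vx)[1:3]
  ad_node(t, value, list(x, w, b), function(g) {
    gm <- matrix(g, n, cout)
    gw <- if (is.environment(w)) crossprod(col, gm) else NULL
    gb <- if (is.environment(b)) colSums(gm) else NULL
    gx <- NULL
    if (is.environment(x)) {
      if (stride == 1L) {
        gp <- pad3(g, kv - 1L - pb, kv - 1L - pa)
        cib <- conv_index(dim(gp)[1:3], k, 1L, cout)
        wf <- flip_weight(vw, kv, cin, cout)
        gx <- col_gather(gp, cib) %*% wf
        dim(gx) <- c(in_sp, cin)
      } else {
        gcol <- tcrossprod(gm, vw)
        gxp <- col_scatter(gcol, ci, pdims)
        gx <- crop3(gxp, pb, pa)
      }
    }
    list(gx, gw, gb)
  })
}

# transposed 3D convolution: exact adjoint of ad_conv3d with the same
# (k, stride, pad); maps a coarse grid up to out_sp spatial dims.
# w: flat (k^3 * cout, cin); b: length-cout.
ad_convt3d <- function(t, x, w, b, k, stride, pad, out_sp) {
  vx <- ad_val(x); vw <- ad_val(w); vb <- ad_val(b)
  pb <- pad[1]; pa <- if (length(pad) > 1) pad[2] else pad[1]
  cin <- dim(vx)[4]
  cout <- nrow(vw) %/% (k^3)
  pdims <- c(out_sp + pb + pa, cout)
  ci <- conv_index(pdims[1:3], k, stride, cout)
  n <- ci$n
  stopifnot(n == prod(dim(vx)[1:3]))
  xm <- matrix(vx, n, cin)
  colm <- tcrossprod(xm, vw)            # n x (k^3 * cout)
  yp <- col_scatter(colm, ci, pdims)
  y <- crop3(yp, pb, pa)
  if (!is.null(vb)) y <- y + rep(vb, each = prod(out_sp))
  ad_node(t, y, list(x, w, b), function(g) {
    gp <- pad3(g, pb, pa)
    gcol <- col_gather(gp, ci)
    gx <- if (is.environment(x)) array(gcol %*% vw, dim(vx)) else NULL
    gw <- if (is.environment(w)) crossprod(gcol, xm) else NULL
    gb <- if (is.environment(b))
      colSums(matrix(g, prod(out_sp), cout)) else NULL
    list(gx, gw, gb)
  })
}

# instance normalization: per-channel standardization over spatial dims,
# learnable gain/shift
ad_instnorm <- function(t, x, gamma, beta, eps = 1e-5) {
  vx <- ad_val(x); vg <- ad_val(gamma); vb <- ad_val(beta)
  d <- dim(vx)
  n <- prod(d[1:3]); ch <- d[4]
  xm <- matrix(vx, n, ch)
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  std <- sqrt(va + eps)
  xhat <- (xm - rep(mu, each = n)) / rep(std, each = n)
  y <- xhat * rep(vg, each = n) + rep(vb, each = n)
  ad_node(t, array(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, n, ch)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- gm * rep(vg, each = n)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dx <- (dxh - rep(m1, each = n) - xhat * rep(m2, each = n)) /
      rep(std, each = n)
    list(array(dx, d), dgamma, dbeta)
  })
}

# fully connected map of a flattened feature block to n_out scalars
ad_linear <- function(t, x, w, b) {
  vx <- ad_val(x); vw <- ad_val(w); vb <- ad_val(b)
  xv <- as.vector(vx)
  y <- as.vector(vw %*% xv + vb)
  d <- dim(vx)
  ad_node(t, y, list(x, w, b), function(g) {
    list(array(crossprod(vw, g), d), g %o% xv, g)
  })
}
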