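#' Configure a training run
#'
#' Defaults follow the method's stated settings: Adam with learning rate
#' 2e-4, reconstruction weight `alpha = 33`, dropout 0.2 in the refiner
#' blocks. Adam betas default to (0.5, 0.999), the usual GAN-stable choice;
#' both networks share one learning rate; update order is one discriminator
#' step then one generator step per iteration; training stops at the fixed
#' step budget.
#'
#' @param learning_rate Adam step size, > 0.
#' @param adam_betas numeric `(beta1, beta2)`.
#' @param batch_size items averaged per optimization step.
#' @param steps total alternating steps.
#' @param alpha reconstruction weight forwarded into the loss config.
#' @param dropout refiner dropout forwarded into the generator config.
#' @param seed master RNG seed for the run (parameter init uses
#'   `seed + 1` / `seed + 2` for G / D).
#' @param adversarial `FALSE` trains the generator alone on the
#'   reconstruction loss (no discriminator), used for overfit checks.
#' @param checkpoint_every write a checkpoint every so many steps into
#'   `out_dir` (requires `out_dir`); `Inf` disables.
#' @param out_dir optional run directory for checkpoints and the loss log.
#' @param device `"cpu"` (the only backend provided).
#' @return a `voxgan_train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, adam_betas = c(0.5, 0.999),
                         batch_size = 1L, steps = 500L, alpha = 33,
                         dropout = 0.2, seed = 1L, adversarial = TRUE,
                         checkpoint_every = Inf, out_dir = NULL,
                         device = "cpu") {
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  device <- match.arg(device, "cpu")
  structure(list(learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), alpha = alpha, dropout = dropout,
                 seed = as.integer(seed), adversarial = isTRUE(adversarial),
                 checkpoint_every = checkpoint_every, out_dir = out_dir,
                 device = device),
            class = "voxgan_train_config")
}

## ---- Adam ----

# optimizer moments live in an environment to avoid per-step list copies
adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e
}

adam_step <- function(params, grads, st, lr, betas, eps = 1e-8) {
  st$t <- st$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]
    m <- if (is.null(m)) (1 - b1) * g else b1 * m + (1 - b1) * g
    v <- st$v[[nm]]
    v <- if (is.null(v)) (1 - b2) * g * g else b2 * v + (1 - b2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  list(params = params, state = st)
}

# environments do not serialize by value with the rest of the state; turn
# moments into plain lists for checkpointing and back on load
adam_freeze <- function(st)
  list(t = st$t, m = as.list(st$m), v = as.list(st$v))

adam_thaw <- function(fr) {
  if (is.environment(fr)) return(fr)
  e <- adam_state()
  e$t <- fr$t
  for (nm in names(fr$m)) e$m[[nm]] <- fr$m[[nm]]
  for (nm in names(fr$v)) e$v[[nm]] <- fr$v[[nm]]
  e
}

## ---- differentiable reconstruction loss graph ----

# builds the soft-feature + exact L1 + exact slice-SSIM objective on the
# tape; truth is a plain (l, w, h, 1) array, fake a node of the same shape.
# Returns nodes for each term; the feature term uses the sigmoid surrogate
# (hard value reported separately by the caller).
recon_loss_nodes <- function(tape, truth, fake, cfg) {
  d <- dim(truth)
  l_dist <- ad_mean(tape, ad_abs(tape, ad_sub(tape, fake, truth)))
  # soft feature term
  tau <- cfg$soft_sharpness
  miss <- NULL
  for (tt in cfg$thresholds) {
    a <- plogis((truth - tt) * tau)             # constant soft indicator
    b <- ad_sigmoid(tape, ad_affine(tape, fake, tau, -tau * tt))
    inter <- ad_sum(tape, ad_mul(tape, b, a))
    uni <- ad_sub(tape, ad_affine(tape, ad_sum(tape, b), 1, sum(a)), inter)
    m <- ad_affine(tape, ad_div(tape, inter, uni), -1, 1)
    miss <- if (is.null(miss)) m else ad_add(tape, miss, m)
  }
  nr <- length(cfg$thresholds)
  l_feat_soft <- if (cfg$normalize_feature_by_nr && nr > 1L)
    ad_affine(tape, miss, 1 / nr, 0) else miss
  # exact slice-wise SSIM via a win x win x 1 Gaussian valid filter
  win <- effective_window(cfg$ssim_window, d)
  g1 <- gaussian_kernel_1d(win, cfg$ssim_sigma)
  gw <- matrix(as.vector(outer(g1, g1)), ncol = 1)   # (win^2 * 1, 1)
  kvec <- c(win, win, 1L)
  gfilt <- function(x) ad_conv3d(tape, x, gw, NULL, kvec, 1L, c(0L, 0L))
  gfilt_c <- function(x) {   # constant-path filter (plain arrays)
    ci <- conv_index(d[1:3], kvec, 1L, 1L)
    array(col_gather(x, ci) %*% gw, c(ci$odims, 1L))
  }
  c1 <- cfg$ssim_k1^2; c2 <- cfg$ssim_k2^2
  mu1 <- gfilt_c(truth)
  s11 <- gfilt_c(truth * truth) - mu1 * mu1
  mu2 <- gfilt(fake)
  mu22 <- ad_mul(tape, mu2, mu2)
  s22 <- ad_sub(tape, gfilt(ad_mul(tape, fake, fake)), mu22)
  s12 <- ad_sub(tape, gfilt(ad_mul(tape, fake, truth)),
                ad_mul(tape, mu2, mu1))
  num <- ad_mul(tape,
                ad_affine(tape, ad_mul(tape, mu2, 2 * mu1), 1, c1),
                ad_affine(tape, s12, 2, c2))
  den <- ad_mul(tape,
                ad_affine(tape, ad_add(tape, mu22, mu1 * mu1), 1, c1),
                ad_affine(tape, ad_add(tape, s11, s22), 1, c2))
  l_sim <- ad_affine(tape, ad_mean(tape, ad_div(tape, num, den)), -1, 1)
  l_recon <- ad_add(tape, ad_add(tape, l_dist, l_feat_soft), l_sim)
  list(l_dist = l_dist, l_feat_soft = l_feat_soft, l_sim = l_sim,
       l_recon = l_recon)
}

wrap_params <- function(tape, params)
  lapply(params, function(p) ad_leaf(tape, p))

collect_grads <- function(pnodes)
  lapply(pnodes, function(nd) nd$grad)

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g))
    if (!is.null(g[[nm]]))
      acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  acc
}

#' Train the conditional volume GAN
#'
#' Alternates one discriminator step (least-squares loss on the real and
#' the detached generated volume) and one generator step (adversarial term
#' plus `alpha` times the reconstruction loss, with the soft feature
#' surrogate) per iteration, Adam for both. Items are consumed in cycling
#' order; the whole run is deterministic given the config seed. The per-step
#' log always reports hard-indicator loss values.
#'
#' @param dataset list of phantom pairs (or any list of elements with
#'   `$truth` volume and `$condition` image set) sharing one resolution.
#' @param gen_cfg,disc_cfg,loss_cfg,train_cfg configuration objects; the
#'   training config's `alpha` and `dropout` override the loss/generator
#'   configs.
#' @param state optional `voxgan_train_state` to resume from.
#' @param verbose print a loss line every 50 steps.
#' @return a `voxgan_train_state`: networks, optimizer moments, RNG state
#'   and the loss log (`data.frame` with columns step, l_dist, l_feat,
#'   l_sim, l_recon, l_adv_g, l_g_total, l_d).
#' @export
train <- function(dataset, gen_cfg = generator_config(),
                  disc_cfg = discriminator_config(),
                  loss_cfg = loss_config(), train_cfg = train_config(),
                  state = NULL, verbose = FALSE) {
  if (length(dataset) < 1L) stop("dataset is empty", call. = FALSE)
  loss_cfg$alpha <- train_cfg$alpha
  gen_cfg$dropout <- train_cfg$dropout
  res <- gen_cfg$out_resolution
  for (i in seq_along(dataset))
    if (!identical(dim(dataset[[i]]$truth), as.integer(res)))
      stop(sprintf("dataset item %d has shape (%s), expected (%s)", i,
                   paste(dim(dataset[[i]]$truth), collapse = ","),
                   paste(res, collapse = ",")), call. = FALSE)
  adv <- train_cfg$adversarial
  if (is.null(state)) {
    set.seed(train_cfg$seed)
    G <- build_generator(gen_cfg, train_cfg$seed + 1L)
    D <- if (adv) build_discriminator(disc_cfg, train_cfg$seed + 2L) else NULL
    opt_g <- adam_state()
    opt_d <- adam_state()
    step0 <- 0L
    log <- NULL
  } else {
    G <- state$G; D <- state$D
    opt_g <- adam_thaw(state$opt_g); opt_d <- adam_thaw(state$opt_d)
    step0 <- state$step
    log <- state$log
    assign(".Random.seed", state$rng, envir = globalenv())
  }
  n <- length(dataset)
  bs <- train_cfg$batch_size
  lr <- train_cfg$learning_rate
  betas <- train_cfg$adam_betas
  conds <- lapply(dataset, function(it)
    condition_tensor(it$condition, res))
  truths <- lapply(dataset, function(it)
    array(unclass(it$truth), c(res, 1L)))
  newlog <- matrix(NA_real_, train_cfg$steps, 8L)
  colnames(newlog) <- c("step", "l_dist", "l_feat", "l_sim", "l_recon",
                        "l_adv_g", "l_g_total", "l_d")
  for (s in seq_len(train_cfg$steps)) {
    step <- step0 + s
    items <- ((step - 1L) * bs + seq_len(bs) - 1L) %% n + 1L
    fakes <- vector("list", bs)
    tapes <- vector("list", bs)
    pg <- vector("list", bs)
    for (j in seq_len(bs)) {
      tp <- ad_tape()
      pn <- wrap_params(tp, G$params)
      fakes[[j]] <- gen_forward_node(tp, pn, G$cfg, conds[[items[j]]],
                                     train = TRUE)
      tapes[[j]] <- tp
      pg[[j]] <- pn
    }
    l_d <- NA_real_
    if (adv) {
      gacc <- NULL
      l_d <- 0
      for (j in seq_len(bs)) {
        td <- ad_tape()
        pd <- wrap_params(td, D$params)
        dr <- disc_forward_node(td, pd, D$cfg, conds[[items[j]]],
                                truths[[items[j]]])
        df <- disc_forward_node(td, pd, D$cfg, conds[[items[j]]],
                                ad_val(fakes[[j]]))
        tgt <- if (loss_cfg$lsgan_targets == "standard") 1 else 0.5
        ld <- ad_add(td,
                     ad_affine(td, ad_mul(td, ad_affine(td, dr, 1, -tgt),
                                          ad_affine(td, dr, 1, -tgt)), 1, 0),
                     ad_mul(td, df, df))
        ad_backward(td, ld)
        gacc <- acc_grads(gacc, collect_grads(pd))
        l_d <- l_d + ad_val(ld)
      }
      l_d <- l_d / bs
      if (!is.finite(l_d))
        stop(sprintf("discriminator loss non-finite at step %d", step),
             call. = FALSE)
      if (bs > 1L) gacc <- lapply(gacc, function(g) g / bs)
      upd <- adam_step(D$params, gacc, opt_d, lr, betas)
      D$params <- upd$params
      opt_d <- upd$state
    }
    # generator step (against the updated discriminator)
    gaccg <- NULL
    comp <- c(l_dist = 0, l_feat = 0, l_sim = 0, l_adv_g = 0)
    for (j in seq_len(bs)) {
      tp <- tapes[[j]]
      rl <- recon_loss_nodes(tp, truths[[items[j]]], fakes[[j]], loss_cfg)
      if (adv) {
        df2 <- disc_forward_node(tp, D$params, D$cfg, conds[[items[j]]],
                                 fakes[[j]])
        tgt <- if (loss_cfg$lsgan_targets == "standard") 1 else 0.5
        ladv <- ad_mul(tp, ad_affine(tp, df2, 1, -tgt),
                       ad_affine(tp, df2, 1, -tgt))
        lg <- ad_add(tp, ladv, ad_affine(tp, rl$l_recon, loss_cfg$alpha, 0))
      } else {
        ladv <- NULL
        lg <- rl$l_recon
      }
      if (!is.finite(ad_val(lg)))
        stop(sprintf("generator loss non-finite at step %d", step),
             call. = FALSE)
      ad_backward(tp, lg)
      gaccg <- acc_grads(gaccg, collect_grads(pg[[j]]))
      fk <- array(ad_val(fakes[[j]]), res)
      tr <- array(truths[[items[j]]], res)
      comp["l_dist"] <- comp["l_dist"] + ad_val(rl$l_dist)
      comp["l_feat"] <- comp["l_feat"] + feature_loss(tr, fk, loss_cfg)
      comp["l_sim"] <- comp["l_sim"] + ad_val(rl$l_sim)
      comp["l_adv_g"] <- comp["l_adv_g"] +
        if (adv) ad_val(ladv) else NA_real_
    }
    comp <- comp / bs
    if (bs > 1L) gaccg <- lapply(gaccg, function(g) g / bs)
    upd <- adam_step(G$params, gaccg, opt_g, lr, betas)
    G$params <- upd$params
    opt_g <- upd$state
    l_recon <- comp["l_dist"] + comp["l_feat"] + comp["l_sim"]
    newlog[s, ] <- c(step, comp["l_dist"], comp["l_feat"], comp["l_sim"],
                     l_recon,
                     comp["l_adv_g"],
                     if (adv) comp["l_adv_g"] + loss_cfg$alpha * l_recon
                     else loss_cfg$alpha * l_recon,
                     l_d)
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d: l_recon %.4f l_d %s", step, l_recon,
                      format(l_d, digits = 4)))
    if (is.finite(train_cfg$checkpoint_every) &&
        step %% train_cfg$checkpoint_every == 0L &&
        !is.null(train_cfg$out_dir)) {
      st <- make_state(step, G, D, opt_g, opt_d,
                       rbind(log, newlog[seq_len(s), , drop = FALSE]),
                       loss_cfg, train_cfg)
      save_checkpoint(st, file.path(train_cfg$out_dir,
                                    sprintf("checkpoint_%06d.rds", step)))
    }
  }
  st <- make_state(step0 + train_cfg$steps, G, D, opt_g, opt_d,
                   rbind(log, newlog), loss_cfg, train_cfg)
  if (!is.null(train_cfg$out_dir)) {
    if (!dir.exists(train_cfg$out_dir))
      dir.create(train_cfg$out_dir, recursive = TRUE)
    utils::write.csv(st$log, file.path(train_cfg$out_dir, "loss_log.csv"),
                     row.names = FALSE)
  }
  st
}

make_state <- function(step, G, D, opt_g, opt_d, log, loss_cfg, train_cfg) {
  structure(list(step = step, G = G, D = D,
                 opt_g = adam_freeze(opt_g), opt_d = adam_freeze(opt_d),
                 log = as.data.frame(log), loss_cfg = loss_cfg,
                 train_cfg = train_cfg,
                 rng = get(".Random.seed", envir = globalenv())),
            class = "voxgan_train_state")
}

#' @export
print.voxgan_train_state <- function(x, ...) {
  cat(sprintf("<voxgan_train_state> step %d, %s\n", x$step,
              if (is.null(x$D)) "generator-only" else "adversarial"))
  if (nrow(x$log) > 0) {
    tail1 <- x$log[nrow(x$log), ]
    cat(sprintf("  last losses: l_recon %.4f l_dist %.4f l_feat %.4f l_sim %.4f\n",
                tail1$l_recon, tail1$l_dist, tail1$l_feat, tail1$l_sim))
  }
  invisible(x)
}

#' Generate a volume from a trained state or checkpoint
#'
#' Evaluation-mode forward (dropout off): repeated calls with the same
#' checkpoint and condition are bit-identical.
#'
#' @param state a `voxgan_train_state` or path to a saved checkpoint.
#' @param condition a `voxgan_image_set` on the generator's grid.
#' @return a `voxgan_volume`.
#' @export
generate <- function(state, condition) {
  if (is.character(state)) state <- load_checkpoint(state)
  if (!inherits(state, "voxgan_train_state"))
    stop("state must be a voxgan_train_state or checkpoint path",
         call. = FALSE)
  generator_forward(state$G, condition, train = FALSE)
}

#' Save / load a training checkpoint
#'
#' The checkpoint is an RDS of the full training state (parameters,
#' optimizer moments, RNG state, configs) plus a human-readable JSON
#' sidecar (`<path>.json`) recording configs, seed and step. Loading and
#' generating reproduces generation before saving bit-exactly on the same
#' machine.
#'
#' @param state a `voxgan_train_state`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` / the restored state.
#' @export
save_checkpoint <- function(state, path) {
  if (!dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  saveRDS(state, path)
  sidecar <- list(step = state$step,
                  seed = state$train_cfg$seed,
                  generator = unclass(state$G$cfg),
                  discriminator = if (!is.null(state$D))
                    unclass(state$D$cfg),
                  loss = unclass(state$loss_cfg),
                  train = unclass(state$train_cfg))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path, call. = FALSE)
  st <- readRDS(path)
  if (!inherits(st, "voxgan_train_state"))
    stop("file is not a voxgan checkpoint: ", path, call. = FALSE)
  st
}
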