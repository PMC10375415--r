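#' Model configuration for the dose estimator
#'
#' Hyperparameters of the fully connected encoder--decoder: LeakyReLU
#' slope 0.2 on hidden layers, tanh on the output, mean squared error
#' loss, Adam with 200 epochs and batch size 4. Encoder/decoder widths
#' are the free capacity knobs.
#'
#' @param encoder_hidden Hidden widths of the current encoder.
#' @param latent Width of the current latent.
#' @param ct_hidden Hidden widths of the density-grid encoder (with-CT
#'   models only).
#' @param ct_latent Width of the density latent.
#' @param decoder_hidden Hidden widths of the decoder trunk.
#' @param alpha LeakyReLU negative slope.
#' @param lr Adam learning rate.
#' @param lr_schedule `"constant"` or `"cosine"` (anneals to lr/50 over
#'   the epochs).
#' @param epochs Training epochs.
#' @param batch Batch size.
#' @param ct_pool Block-average pooling factor applied to the density
#'   grid before its encoder.
#' @param input_transform `"scale"` (divide currents by the training
#'   99th percentile) or `"log"` (additionally log-compress the dynamic
#'   range).
#' @param input_noise_sd Training-time Gaussian jitter added to the
#'   normalized currents (a regularizer emulating detector measurement
#'   noise; 0 disables).
#' @param val_every Epoch interval of the validation pass (the best
#'   checkpoint is chosen among evaluated epochs).
#' @return Object of class `model_config`.
#' @export
model_config <- function(encoder_hidden = 128, latent = 256,
                         ct_hidden = integer(), ct_latent = 128,
                         decoder_hidden = 256, alpha = 0.2,
                         lr = 2e-4, lr_schedule = c("constant",
                                                    "cosine"),
                         epochs = 200, batch = 4, ct_pool = 2L,
                         input_transform = c("scale", "log"),
                         input_noise_sd = 0, val_every = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  input_transform <- match.arg(input_transform)
  stopifnot(alpha > 0, lr > 0, epochs >= 1, batch >= 1)
  structure(list(encoder_hidden = encoder_hidden, latent = latent,
                 ct_hidden = ct_hidden, ct_latent = ct_latent,
                 decoder_hidden = decoder_hidden, alpha = alpha,
                 lr = lr, lr_schedule = lr_schedule,
                 epochs = as.integer(epochs),
                 batch = as.integer(batch),
                 ct_pool = as.integer(ct_pool),
                 input_transform = input_transform,
                 input_noise_sd = input_noise_sd,
                 val_every = as.integer(val_every)),
            class = "model_config")
}

# He-style initialization for a dense layer
init_layer <- function(d_in, d_out, act) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                  d_in, d_out),
       b = numeric(d_out), act = act)
}

init_stack <- function(d_in, widths, acts) {
  layers <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    layers[[i]] <- init_layer(d_in, widths[i], acts[i])
    d_in <- widths[i]
  }
  layers
}

#' Build a dose-estimation model
#'
#' Currents pass through a fully connected encoder to a latent vector;
#' with `with_ct` the (pooled) density grid passes through its own
#' encoder and the two latents are concatenated; the decoder trunk maps
#' the latent to the flattened dose grid through a final tanh, so raw
#' outputs live in (-1, 1) and are de-normalized at prediction time.
#'
#' @param cfg A `model_config`.
#' @param current_dim Length of the current vector.
#' @param target_dim Prod of the target grid dimensions.
#' @param target_shape Integer vector: the target grid dimensions.
#' @param with_ct Condition on the density grid?
#' @param ct_dim Length of the pooled, flattened density grid (required
#'   when `with_ct`).
#' @return Object of class `dose_model` (untrained).
#' @export
build_model <- function(cfg, current_dim, target_dim, target_shape,
                        with_ct = FALSE, ct_dim = NULL) {
  stopifnot(inherits(cfg, "model_config"),
            prod(target_shape) == target_dim)
  enc_w <- c(cfg$encoder_hidden, cfg$latent)
  enc <- init_stack(current_dim, enc_w, rep("lrelu", length(enc_w)))
  ct_enc <- NULL
  lat <- cfg$latent
  if (with_ct) {
    if (is.null(ct_dim)) stop("ct_dim required for with_ct models",
                              call. = FALSE)
    ct_w <- c(cfg$ct_hidden, cfg$ct_latent)
    ct_enc <- init_stack(ct_dim, ct_w, rep("lrelu", length(ct_w)))
    lat <- lat + cfg$ct_latent
  }
  dec_w <- c(cfg$decoder_hidden, target_dim)
  dec <- init_stack(lat, dec_w,
                    c(rep("lrelu", length(dec_w) - 1), "tanh"))
  structure(list(encoder = enc, ct_encoder = ct_enc, decoder = dec,
                 cfg = cfg, with_ct = with_ct,
                 current_dim = current_dim, ct_dim = ct_dim,
                 target_dim = target_dim, target_shape = target_shape,
                 norms = NULL, trained = FALSE),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  np <- sum(vapply(c(x$encoder, x$ct_encoder, x$decoder),
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf(
    "dose model: %d currents%s -> %s grid; %.2fM parameters; %s\n",
    x$current_dim, if (x$with_ct) " + density grid" else "",
    paste(x$target_shape, collapse = "x"), np / 1e6,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

act_fwd <- function(z, act, alpha) {
  switch(act,
         lrelu = cpp_lrelu(z, alpha),
         tanh = tanh(z),
         linear = z)
}

stack_forward <- function(layers, X, alpha) {
  zs <- as_ <- vector("list", length(layers))
  a <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    z <- a %*% l$W
    z <- z + rep(l$b, each = nrow(z))
    a <- act_fwd(z, l$act, alpha)
    zs[[i]] <- z; as_[[i]] <- a
  }
  list(z = zs, a = as_, out = a)
}

# returns gradient lists plus (optionally) the gradient w.r.t. the
# stack input; all matrix products run through BLAS without explicit
# transposition
stack_backward <- function(layers, X, fwd, dout, alpha,
                           need_input = TRUE) {
  grads <- vector("list", length(layers))
  delta <- dout
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$act == "lrelu") cpp_lrelu_bwd(delta, fwd$z[[i]], alpha)
    else if (l$act == "tanh") delta <- delta * (1 - fwd$a[[i]]^2)
    a_prev <- if (i == 1) X else fwd$a[[i - 1]]
    grads[[i]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (i > 1 || need_input) delta <- tcrossprod(delta, l$W)
  }
  list(grads = grads, dinput = if (need_input) delta)
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0,
         mb = l$b * 0, vb = l$b * 0))
}

# Adam updates weights and moments in place (C++ kernels); layers and
# state must be exclusively owned by the caller (checkpoints are
# deep-copied).
adam_step <- function(layers, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]; s <- state[[i]]
    cpp_adam_update(layers[[i]]$W, g$W, s$mW, s$vW, lr, t, b1, b2, eps)
    cpp_adam_update(layers[[i]]$b, g$b, s$mb, s$vb, lr, t, b1, b2, eps)
  }
  list(layers = layers, state = state)
}

deep_copy_layers <- function(layers) {
  lapply(layers, function(l) list(W = l$W + 0, b = l$b + 0,
                                  act = l$act))
}

model_forward <- function(model, X, XCT = NULL) {
  alpha <- model$cfg$alpha
  fe <- stack_forward(model$encoder, X, alpha)
  if (model$with_ct) {
    fc <- stack_forward(model$ct_encoder, XCT, alpha)
    h <- cbind(fe$out, fc$out)
  } else {
    fc <- NULL
    h <- fe$out
  }
  fd <- stack_forward(model$decoder, h, alpha)
  list(fe = fe, fc = fc, fd = fd, h = h, out = fd$out)
}

#' Train a dose model
#'
#' Minimizes the mean squared error on normalized targets with Adam
#' (batch size and epoch count from the model's `model_config`),
#' shuffling each epoch, evaluating the validation loss after every
#' epoch and retaining the best-validation weights. Training diverging
#' to a non-finite loss aborts with a diagnostic. Deterministic given
#' the R random seed.
#'
#' @param model An untrained `dose_model`.
#' @param train,val Lists of dataset samples (from a `dose_dataset`,
#'   possibly flip-augmented).
#' @param quiet Suppress the per-epoch progress line.
#' @return The trained model, with `$history` (per-epoch train/val loss)
#'   and serialized normalization constants.
#' @export
train_model <- function(model, train, val, quiet = TRUE) {
  stopifnot(inherits(model, "dose_model"), length(train) >= 1)
  cfg <- model$cfg
  # optimizer updates run in place; detach from the caller's object
  model$encoder <- deep_copy_layers(model$encoder)
  if (model$with_ct) model$ct_encoder <- deep_copy_layers(model$ct_encoder)
  model$decoder <- deep_copy_layers(model$decoder)
  tr <- dataset_matrices(train, with_ct = model$with_ct,
                         ct_pool = cfg$ct_pool)
  va <- dataset_matrices(val, with_ct = model$with_ct,
                         ct_pool = cfg$ct_pool)
  norms <- fit_normalization(tr)
  model$norms <- norms
  X <- normalize_inputs(tr$X, norms, cfg$input_transform)
  Y <- normalize_targets(tr$Y, norms)
  XV <- normalize_inputs(va$X, norms, cfg$input_transform)
  YV <- normalize_targets(va$Y, norms)
  XCT <- if (model$with_ct) tr$XCT / norms$ct_scale
  XCTV <- if (model$with_ct) va$XCT / norms$ct_scale

  # start the output layer at the per-voxel training mean (mostly the
  # -1 background), so early epochs refine structure instead of
  # learning the base rate
  nl <- length(model$decoder)
  out_tanh <- model$decoder[[nl]]$act == "tanh"
  if (out_tanh)
    model$decoder[[nl]]$b <- atanh(pmin(pmax(colMeans(Y), -0.98),
                                        0.98))
  # the output layer carries most parameters; it trains through the
  # fused single-precision kernel
  outp <- cpp_out_create(model$decoder[[nl]]$W, model$decoder[[nl]]$b)
  dec_hidden <- model$decoder[-nl]
  st_e <- adam_init(model$encoder)
  st_c <- if (model$with_ct) adam_init(model$ct_encoder)
  st_d <- adam_init(dec_hidden)
  n <- nrow(X)
  hist_tr <- hist_va <- numeric(cfg$epochs)
  best <- list(loss = Inf)
  t_adam <- 0
  fwd_to_out <- function(Xin, XCTin) {
    fe <- stack_forward(model$encoder, Xin, cfg$alpha)
    fc <- NULL
    h <- fe$out
    if (model$with_ct) {
      fc <- stack_forward(model$ct_encoder, XCTin, cfg$alpha)
      h <- cbind(fe$out, fc$out)
    }
    fh <- if (length(dec_hidden))
      stack_forward(dec_hidden, h, cfg$alpha)
    hin <- if (length(dec_hidden)) fh$out else h
    list(fe = fe, fc = fc, fh = fh, h = h, hin = hin,
         out = cpp_out_forward(outp, hin, out_tanh))
  }
  val_loss <- function() {
    if (!nrow(XV)) return(NA_real_)
    mean((fwd_to_out(XV, XCTV)$out - YV)^2)
  }
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- if (identical(cfg$lr_schedule, "cosine"))
      cfg$lr * (0.01 + 0.99 * 0.5 *
                  (1 + cos(pi * (ep - 1) / max(cfg$epochs - 1, 1))))
    else cfg$lr
    ord <- sample.int(n)
    ep_loss <- 0
    for (k in seq_len(ceiling(n / cfg$batch))) {
      rows <- ord[((k - 1) * cfg$batch + 1):min(k * cfg$batch, n)]
      xb <- X[rows, , drop = FALSE]
      if (cfg$input_noise_sd > 0)
        xb <- xb + stats::rnorm(length(xb), sd = cfg$input_noise_sd)
      yb <- Y[rows, , drop = FALSE]
      cb <- if (model$with_ct) XCT[rows, , drop = FALSE]
      f <- fwd_to_out(xb, cb)
      err <- f$out - yb
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      ep_loss <- ep_loss + loss * length(rows)
      dout <- 2 * err / length(err)
      t_adam <- t_adam + 1
      dhin <- cpp_out_backward(outp, f$hin, f$out, dout, out_tanh)
      cpp_out_adam(outp, lr_ep, t_adam, 0.9, 0.999, 1e-8)
      dh <- if (length(dec_hidden)) {
        bd <- stack_backward(dec_hidden, f$h, f$fh, dhin, cfg$alpha)
        up <- adam_step(dec_hidden, bd$grads, st_d, lr_ep, t_adam)
        dec_hidden <- up$layers; st_d <- up$state
        bd$dinput
      } else dhin
      dl <- ncol(f$fe$out)
      de <- stack_backward(model$encoder, xb, f$fe,
                           dh[, seq_len(dl), drop = FALSE],
                           cfg$alpha, need_input = FALSE)
      up <- adam_step(model$encoder, de$grads, st_e, lr_ep, t_adam)
      model$encoder <- up$layers; st_e <- up$state
      if (model$with_ct) {
        dc <- stack_backward(model$ct_encoder, cb, f$fc,
                             dh[, -seq_len(dl), drop = FALSE],
                             cfg$alpha, need_input = FALSE)
        up <- adam_step(model$ct_encoder, dc$grads, st_c, lr_ep,
                        t_adam)
        model$ct_encoder <- up$layers; st_c <- up$state
      }
    }
    hist_tr[ep] <- ep_loss / n
    evaluated <- ep %% cfg$val_every == 0 || ep == cfg$epochs
    hist_va[ep] <- if (evaluated) val_loss() else NA_real_
    vl <- if (!evaluated) Inf
          else if (is.na(hist_va[ep])) hist_tr[ep]
          else hist_va[ep]
    if (vl < best$loss)
      best <- list(loss = vl, encoder = deep_copy_layers(model$encoder),
                   ct_encoder = if (model$with_ct)
                     deep_copy_layers(model$ct_encoder),
                   dec_hidden = deep_copy_layers(dec_hidden),
                   out = cpp_out_export(outp))
    if (!quiet && ep %% 10 == 0)
      cat(sprintf("epoch %3d  train %.3e  val %.3e\n", ep,
                  hist_tr[ep], hist_va[ep]))
  }
  model$encoder <- best$encoder
  model$ct_encoder <- best$ct_encoder
  out_layer <- model$decoder[[nl]]
  out_layer$W <- best$out$W
  out_layer$b <- as.numeric(best$out$b)
  model$decoder <- c(best$dec_hidden, list(out_layer))
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              train = hist_tr, val = hist_va)
  model$trained <- TRUE
  model
}

#' Predict the dose grid from detector currents
#'
#' De-normalizes the tanh output to the dose scale of the training
#' targets and clips at zero (doses are non-negative). Inference is
#' deterministic.
#'
#' @param object A trained `dose_model`.
#' @param currents Current vector, or a matrix (one sample per row).
#' @param ct Density grid (3D array) or pooled matrix, for with-CT
#'   models.
#' @param ... Unused.
#' @return Dose grid shaped like the training target (list of grids for
#'   matrix input).
#' @export
predict.dose_model <- function(object, currents, ct = NULL, ...) {
  if (!object$trained) stop("model is not trained", call. = FALSE)
  one <- is.null(dim(currents))
  X <- if (one) matrix(currents, 1) else currents
  if (ncol(X) != object$current_dim)
    stop("current vector length mismatch", call. = FALSE)
  XCT <- NULL
  if (object$with_ct) {
    if (is.null(ct)) stop("model requires a density grid", call. = FALSE)
    if (!is.null(dim(ct)) && length(dim(ct)) == 3L)
      ct <- matrix(as.numeric(pool_grid(ct, object$cfg$ct_pool)), 1)
    XCT <- ct / object$norms$ct_scale
    if (ncol(XCT) != object$ct_dim)
      stop("density grid shape mismatch", call. = FALSE)
  }
  out <- model_forward(object,
                       normalize_inputs(X, object$norms,
                                        object$cfg$input_transform),
                       XCT)$out
  out <- denormalize_targets(out, object$norms)
  grids <- lapply(seq_len(nrow(out)), function(i) {
    g <- out[i, ]
    dim(g) <- object$target_shape
    g
  })
  if (one) grids[[1]] else grids
}
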