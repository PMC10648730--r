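# The side-specific 2D U-Net used for kidney segmentation.
#
# Architecture (F = start_feature_maps):
#   encoder (10 conv layers, 3x3, stride 1, ReLU):
#     e1->BN, e2->pool, e3->BN, e4->pool, e5->dropout, e6->pool,
#     e7->BN, e8->pool, e9->BN, e10
#     channel schedule F,F,2F,2F,4F,4F,8F,8F,16F,16F
#   decoder: 4 up-blocks, each a 2x2 stride-2 transpose convolution whose
#     channel count equals the preceding conv output, concatenation with the
#     matching encoder feature map, then 3x3 convs with halved feature count;
#     block conv layout (2,2,2,1); first decoder conv followed by dropout,
#     block-final convs of blocks 1-3 followed by BN; final 1x1 sigmoid conv.
# Totals: 18 conv layers (17 3x3 + one 1x1), 4 max-pools, 4 transpose convs,
# 7 batch normalizations, 2 dropouts.

#' Training hyperparameters
#'
#' The four hyperparameters the genetic algorithm searches over. Defaults are
#' the optimum found by the full-scale genetic search: learning rate 0.15,
#' batch size 12, 32 starting feature maps, dropout rate 0.1.
#'
#' @param learning_rate Adam step size (positive).
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param start_feature_maps Channel count of the first two convolutions
#'   (positive integer; powers of two by convention).
#' @param batch_size Mini-batch size (positive integer).
#' @return An object of class `renalvol_hp`.
#' @export
hyperparameters <- function(learning_rate = 0.15, dropout_rate = 0.1,
                            start_feature_maps = 32, batch_size = 12) {
  stopifnot(learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1,
            start_feature_maps >= 1, batch_size >= 1)
  hp <- list(learning_rate = learning_rate,
             dropout_rate = dropout_rate,
             start_feature_maps = as.integer(round(start_feature_maps)),
             batch_size = as.integer(round(batch_size)))
  class(hp) <- "renalvol_hp"
  hp
}

#' @export
print.renalvol_hp <- function(x, ...) {
  cat(sprintf(
    "Hyperparameters: lr=%g, dropout=%g, start_feature_maps=%d, batch_size=%d\n",
    x$learning_rate, x$dropout_rate, x$start_feature_maps, x$batch_size))
  invisible(x)
}

unet_channel_plan <- function(f) {
  list(
    enc_in  = c(1, f, f, 2 * f, 2 * f, 4 * f, 4 * f, 8 * f, 8 * f, 16 * f),
    enc_out = c(f, f, 2 * f, 2 * f, 4 * f, 4 * f, 8 * f, 8 * f, 16 * f, 16 * f),
    # transpose convs keep the channel count of the preceding conv output
    up_in   = c(16 * f, 8 * f, 4 * f, 2 * f),
    up_out  = c(16 * f, 8 * f, 4 * f, 2 * f),
    skip    = c(8 * f, 4 * f, 2 * f, f),
    # decoder 3x3 convs (blocks of 2,2,2,1), halved feature counts per block
    dec_in  = c(24 * f, 8 * f, 12 * f, 4 * f, 6 * f, 2 * f, 3 * f),
    dec_out = c(8 * f, 8 * f, 4 * f, 4 * f, 2 * f, 2 * f, f)
  )
}

#' Build the kidney-segmentation U-Net
#'
#' Constructs the 18-conv-layer encoder-decoder network with randomly
#' initialised (He-normal) weights.
#'
#' @param hp A [hyperparameters()] object; `start_feature_maps` and
#'   `dropout_rate` shape the network.
#' @param input_shape Integer vector `c(height, width)`; both must be
#'   divisible by 16 (four 2x2 pooling stages).
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class `renalvol_unet`.
#' @examples
#' net <- build_unet(hyperparameters(start_feature_maps = 8), c(64, 32), seed = 1)
#' unet_audit(net)$n_conv_layers  # 18
#' @export
build_unet <- function(hp, input_shape = c(512, 256), seed = NULL) {
  stopifnot(inherits(hp, "renalvol_hp"), length(input_shape) == 2)
  if (any(input_shape %% 16 != 0)) {
    stop("input_shape must be divisible by 16 in both dimensions ",
         "(four 2x2 pooling stages); got ",
         paste(input_shape, collapse = "x"))
  }
  if (!is.null(seed)) set.seed(seed)
  f <- hp$start_feature_maps
  plan <- unet_channel_plan(f)
  p <- list()
  for (i in 1:10) {
    cin <- plan$enc_in[i]; cout <- plan$enc_out[i]
    p[[paste0("e", i, "_w")]] <- he_init(c(3, 3, cin, cout), 9 * cin)
    p[[paste0("e", i, "_b")]] <- numeric(cout)
  }
  for (i in 1:4) {
    cin <- plan$up_in[i]; cout <- plan$up_out[i]
    p[[paste0("u", i, "_w")]] <- he_init(c(2, 2, cin, cout), 4 * cin)
    p[[paste0("u", i, "_b")]] <- numeric(cout)
  }
  for (i in 1:7) {
    cin <- plan$dec_in[i]; cout <- plan$dec_out[i]
    p[[paste0("d", i, "_w")]] <- he_init(c(3, 3, cin, cout), 9 * cin)
    p[[paste0("d", i, "_b")]] <- numeric(cout)
  }
  p$o_w <- he_init(c(f, 1), f)
  p$o_b <- 0
  bn_names <- c("bn_e1", "bn_e3", "bn_e7", "bn_e9", "bn_d2", "bn_d4", "bn_d6")
  bn_ch <- c(plan$enc_out[c(1, 3, 7, 9)], plan$dec_out[c(2, 4, 6)])
  bn <- list()
  for (i in seq_along(bn_names)) {
    ch <- bn_ch[i]
    p[[paste0(bn_names[i], "_gamma")]] <- rep(1, ch)
    p[[paste0(bn_names[i], "_beta")]] <- rep(0, ch)
    bn[[bn_names[i]]] <- list(mean = rep(0, ch), var = rep(1, ch))
  }
  layers <- c("conv3x3", "bn", "conv3x3", "pool",
              "conv3x3", "bn", "conv3x3", "pool",
              "conv3x3", "dropout", "conv3x3", "pool",
              "conv3x3", "bn", "conv3x3", "pool",
              "conv3x3", "bn", "conv3x3",
              "tconv", "concat", "conv3x3", "dropout", "conv3x3", "bn",
              "tconv", "concat", "conv3x3", "conv3x3", "bn",
              "tconv", "concat", "conv3x3", "conv3x3", "bn",
              "tconv", "concat", "conv3x3",
              "conv1x1_sigmoid")
  structure(list(hp = hp, input_shape = as.integer(input_shape),
                 params = p, bn = bn, layers = layers, plan = plan,
                 side = NULL, trained = FALSE),
            class = "renalvol_unet")
}

#' @export
print.renalvol_unet <- function(x, ...) {
  a <- unet_audit(x)
  cat(sprintf(
    "U-Net (%s): input %dx%d, %d conv layers, %d pools, %d transpose convs, %d BN, %d dropout%s\n",
    if (is.null(x$side)) "side unset" else paste0(x$side, " kidney"),
    x$input_shape[1], x$input_shape[2],
    a$n_conv_layers, a$n_maxpool, a$n_transpose, a$n_batchnorm, a$n_dropout,
    if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

#' Structural audit of a built network
#'
#' Counts the operations in the network graph and reports the encoder channel
#' schedule, for verification against the published architecture.
#'
#' @param net A `renalvol_unet`.
#' @return A list with counts (`n_conv_layers` includes the 1x1 output conv),
#'   the encoder feature-map schedule, and the bottleneck spatial shape.
#' @export
unet_audit <- function(net) {
  stopifnot(inherits(net, "renalvol_unet"))
  l <- net$layers
  enc_sched <- vapply(1:10, function(i) dim(net$params[[paste0("e", i, "_w")]])[4],
                      numeric(1))
  list(
    n_conv_layers = sum(l == "conv3x3") + sum(l == "conv1x1_sigmoid"),
    n_conv3x3 = sum(l == "conv3x3"),
    n_conv1x1 = sum(l == "conv1x1_sigmoid"),
    n_maxpool = sum(l == "pool"),
    n_transpose = sum(l == "tconv"),
    n_batchnorm = sum(l == "bn"),
    n_dropout = sum(l == "dropout"),
    encoder_schedule = enc_sched,
    bottleneck_shape = net$input_shape %/% 16L
  )
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
}

# Full forward pass. x: (H, W, N, 1). Returns probabilities plus (optionally)
# the cache needed for the backward pass and updated BN running stats.
unet_forward <- function(net, x, training = FALSE, keep_cache = training) {
  P <- net$params
  bn <- net$bn
  drate <- net$hp$dropout_rate
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL

  # net$exact routes the convolutions through the double-precision plain-R
  # implementation (slow; used for gradient verification)
  exact <- isTRUE(net$exact)
  convrelu <- function(name, xin) {
    if (exact) {
      y <- relu_forward(conv3x3_forward_r(xin, P[[paste0(name, "_w")]],
                                          P[[paste0(name, "_b")]]))
      cols <- NULL
    } else {
      out <- .cpp_conv3x3_forward(xin, P[[paste0(name, "_w")]],
                                  P[[paste0(name, "_b")]], keep_cache)
      y <- relu_forward(out$y)
      cols <- out$cols
    }
    if (keep_cache) {
      assign(name, list(x = xin, y = y, cols = cols), envir = cache)
    }
    y
  }
  bnorm <- function(name, xin) {
    out <- batchnorm_forward(xin, P[[paste0(name, "_gamma")]],
                             P[[paste0(name, "_beta")]], bn[[name]], training)
    bn[[name]] <<- out$running
    if (keep_cache) {
      assign(name, list(xhat = out$xhat, inv_sd = out$inv_sd), envir = cache)
    }
    out$y
  }
  drop_fw <- function(name, xin) {
    out <- dropout_forward(xin, drate, training)
    if (keep_cache) assign(name, out$mask, envir = cache)
    out$y
  }
  pool_fw <- function(name, xin) {
    out <- maxpool_forward(xin)
    if (keep_cache) {
      assign(name, list(which = out$which, h = dim(xin)[1L], w = dim(xin)[2L]),
             envir = cache)
    }
    out$y
  }
  tconv_fw <- function(name, xin) {
    y <- tconv2x2_forward(xin, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]])
    if (keep_cache) assign(name, list(x = xin), envir = cache)
    y
  }

  a1 <- convrelu("e1", x);  b1 <- bnorm("bn_e1", a1)
  a2 <- convrelu("e2", b1); p1 <- pool_fw("pool1", a2)
  a3 <- convrelu("e3", p1); b3 <- bnorm("bn_e3", a3)
  a4 <- convrelu("e4", b3); p2 <- pool_fw("pool2", a4)
  a5 <- convrelu("e5", p2); dr1 <- drop_fw("drop1", a5)
  a6 <- convrelu("e6", dr1); p3 <- pool_fw("pool3", a6)
  a7 <- convrelu("e7", p3); b7 <- bnorm("bn_e7", a7)
  a8 <- convrelu("e8", b7); p4 <- pool_fw("pool4", a8)
  a9 <- convrelu("e9", p4); b9 <- bnorm("bn_e9", a9)
  a10 <- convrelu("e10", b9)

  t1 <- tconv_fw("u1", a10); c1 <- concat_ch(t1, a8)
  g1 <- convrelu("d1", c1); dr2 <- drop_fw("drop2", g1)
  g2 <- convrelu("d2", dr2); bb2 <- bnorm("bn_d2", g2)
  t2 <- tconv_fw("u2", bb2); c2 <- concat_ch(t2, a6)
  g3 <- convrelu("d3", c2)
  g4 <- convrelu("d4", g3); bb4 <- bnorm("bn_d4", g4)
  t3 <- tconv_fw("u3", bb4); c3 <- concat_ch(t3, a4)
  g5 <- convrelu("d5", c3)
  g6 <- convrelu("d6", g5); bb6 <- bnorm("bn_d6", g6)
  t4 <- tconv_fw("u4", bb6); c4 <- concat_ch(t4, a2)
  g7 <- convrelu("d7", c4)
  z <- conv1x1_forward(g7, P$o_w, P$o_b)
  p <- sigmoid(z)
  if (keep_cache) assign("out", list(g7 = g7, p = p), envir = cache)
  list(p = p, cache = cache, bn = bn)
}

# Backward pass from the BCE/sigmoid logit gradient. Returns a flat named
# list of gradients matching net$params.
unet_backward <- function(net, cache, dz) {
  P <- net$params
  G <- list()

  exact <- isTRUE(net$exact)
  convrelu_bw <- function(name, dy) {
    cc <- get(name, envir = cache)
    dy <- relu_backward(cc$y, dy)
    out <- if (exact) {
      conv3x3_backward_r(cc$x, P[[paste0(name, "_w")]], dy)
    } else {
      conv3x3_backward(cc$x, P[[paste0(name, "_w")]], dy, cc$cols)
    }
    G[[paste0(name, "_w")]] <<- out$dw
    G[[paste0(name, "_b")]] <<- out$db
    out$dx
  }
  bnorm_bw <- function(name, dy) {
    cc <- get(name, envir = cache)
    out <- batchnorm_backward(cc, P[[paste0(name, "_gamma")]], dy)
    G[[paste0(name, "_gamma")]] <<- out$dgamma
    G[[paste0(name, "_beta")]] <<- out$dbeta
    out$dx
  }
  drop_bw <- function(name, dy) dropout_backward(get(name, envir = cache), dy)
  pool_bw <- function(name, dy) {
    cc <- get(name, envir = cache)
    maxpool_backward(cc$which, dy, cc$h, cc$w)
  }
  tconv_bw <- function(name, dy) {
    cc <- get(name, envir = cache)
    out <- tconv2x2_backward(cc$x, P[[paste0(name, "_w")]], dy)
    G[[paste0(name, "_w")]] <<- out$dw
    G[[paste0(name, "_b")]] <<- out$db
    out$dx
  }
  split_concat <- function(dy, c_up) {
    d <- dim(dy)
    list(up = dy[, , , seq_len(c_up), drop = FALSE],
         skip = dy[, , , (c_up + 1L):d[4L], drop = FALSE])
  }

  oo <- get("out", envir = cache)
  outg <- conv1x1_backward(oo$g7, P$o_w, dz)
  G$o_w <- outg$dw; G$o_b <- outg$db

  f <- net$hp$start_feature_maps
  dg7 <- convrelu_bw("d7", outg$dx)
  s4 <- split_concat(dg7, 2L * f)
  dbb6 <- tconv_bw("u4", s4$up)
  dg6 <- bnorm_bw("bn_d6", dbb6)
  dg5 <- convrelu_bw("d6", dg6)
  dc3 <- convrelu_bw("d5", dg5)
  s3 <- split_concat(dc3, 4L * f)
  dbb4 <- tconv_bw("u3", s3$up)
  dg4 <- bnorm_bw("bn_d4", dbb4)
  dg3 <- convrelu_bw("d4", dg4)
  dc2 <- convrelu_bw("d3", dg3)
  s2 <- split_concat(dc2, 8L * f)
  dbb2 <- tconv_bw("u2", s2$up)
  dg2 <- bnorm_bw("bn_d2", dbb2)
  ddr2 <- convrelu_bw("d2", dg2)
  dg1 <- drop_bw("drop2", ddr2)
  dc1 <- convrelu_bw("d1", dg1)
  s1 <- split_concat(dc1, 16L * f)
  da10 <- tconv_bw("u1", s1$up)

  db9 <- convrelu_bw("e10", da10)
  da9 <- bnorm_bw("bn_e9", db9)
  dp4 <- convrelu_bw("e9", da9)
  da8 <- pool_bw("pool4", dp4) + s1$skip
  db7 <- convrelu_bw("e8", da8)
  da7 <- bnorm_bw("bn_e7", db7)
  dp3 <- convrelu_bw("e7", da7)
  da6 <- pool_bw("pool3", dp3) + s2$skip
  ddr1 <- convrelu_bw("e6", da6)
  da5 <- drop_bw("drop1", ddr1)
  dp2 <- convrelu_bw("e5", da5)
  da4 <- pool_bw("pool2", dp2) + s3$skip
  db3 <- convrelu_bw("e4", da4)
  da3 <- bnorm_bw("bn_e3", db3)
  dp1 <- convrelu_bw("e3", da3)
  da2 <- pool_bw("pool1", dp1) + s4$skip
  db1 <- convrelu_bw("e2", da2)
  da1 <- bnorm_bw("bn_e1", db1)
  convrelu_bw("e1", da1)
  G
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

stack_batch <- function(images) {
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  x <- array(0, c(h, w, length(images), 1L))
  for (i in seq_along(images)) x[, , i, 1L] <- images[[i]]
  x
}

#' Train a side U-Net
#'
#' Trains with the Adam optimiser and mean binary cross-entropy loss on an
#' 80/20 train/validation split of the dataset, with early stopping after
#' `patience` consecutive epochs without improvement of the validation loss.
#' The weights of the best validation epoch are returned.
#'
#' @param net A `renalvol_unet` from [build_unet()].
#' @param dataset A `side_dataset` from [build_training_set()] whose images
#'   match the network's input shape.
#' @param patience Early-stopping patience in epochs (default 30).
#' @param max_epochs Hard cap on training epochs (default 500).
#' @param validation_split Fraction of images held out for validation.
#' @param augment_prob Probability that a training image is augmented in each
#'   epoch (see [augment()]); 0 disables augmentation.
#' @param seed Integer seed controlling the split, shuffling, augmentation and
#'   dropout; fixed seed gives bit-reproducible training on CPU.
#' @param verbose Print per-epoch losses.
#' @return A list with `net` (trained network, best-epoch weights), `history`
#'   (data frame of per-epoch train/validation loss), `best_epoch`,
#'   `best_val_loss` and `stopped_early`.
#' @export
train_unet <- function(net, dataset, patience = 30, max_epochs = 500,
                       validation_split = 0.2, augment_prob = 0.5,
                       seed = 1, verbose = FALSE) {
  stopifnot(inherits(net, "renalvol_unet"))
  slices <- dataset$slices
  if (length(slices) == 0) stop("dataset is empty")
  shp <- dim(slices[[1L]]$image)
  if (!all(shp == net$input_shape)) {
    stop("dataset image shape (", paste(shp, collapse = "x"),
         ") does not match network input shape (",
         paste(net$input_shape, collapse = "x"), ")")
  }
  set.seed(seed)
  n <- length(slices)
  idx <- sample.int(n)
  n_val <- max(1L, round(validation_split * n))
  if (n_val >= n) stop("dataset too small for a train/validation split")
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]

  xval <- stack_batch(lapply(slices[val_idx], `[[`, "image"))
  yval <- stack_batch(lapply(slices[val_idx], `[[`, "mask"))

  bs <- net$hp$batch_size
  opt <- adam_init(net$params)
  best <- list(val = Inf, params = net$params, bn = net$bn, epoch = 0L)
  since_improve <- 0L
  hist_train <- hist_val <- numeric(0)
  stopped_early <- FALSE

  for (epoch in seq_len(max_epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, length(ord), by = bs)) {
      bidx <- ord[start:min(start + bs - 1L, length(ord))]
      imgs <- vector("list", length(bidx))
      msks <- vector("list", length(bidx))
      for (k in seq_along(bidx)) {
        s <- slices[[bidx[k]]]
        if (augment_prob > 0) {
          aug <- augment(s$image, s$mask, probability = augment_prob)
          imgs[[k]] <- aug$image; msks[[k]] <- aug$mask
        } else {
          imgs[[k]] <- s$image; msks[[k]] <- s$mask
        }
      }
      x <- stack_batch(imgs)
      y <- stack_batch(msks)
      fw <- unet_forward(net, x, training = TRUE)
      net$bn <- fw$bn
      loss <- bce_loss(fw$p, y)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      ep_loss <- ep_loss + loss * length(bidx)
      ep_n <- ep_n + length(bidx)
      grads <- unet_backward(net, fw$cache, bce_sigmoid_grad(fw$p, y))
      upd <- adam_step(net$params, grads, opt, net$hp$learning_rate)
      net$params <- upd$params
      opt <- upd$state
    }
    vw <- unet_forward(net, xval, training = FALSE, keep_cache = FALSE)
    val_loss <- bce_loss(vw$p, yval)
    if (!is.finite(val_loss)) {
      stop("training diverged: non-finite validation loss at epoch ", epoch)
    }
    hist_train <- c(hist_train, ep_loss / ep_n)
    hist_val <- c(hist_val, val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / ep_n, val_loss))
    }
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = net$params, bn = net$bn,
                   epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  net$params <- best$params
  net$bn <- best$bn
  net$trained <- TRUE
  list(net = net,
       history = data.frame(epoch = seq_along(hist_train),
                            train_loss = hist_train, val_loss = hist_val),
       best_epoch = best$epoch, best_val_loss = best$val,
       stopped_early = stopped_early)
}

#' Save / load a trained model
#'
#' The model is serialized with [saveRDS()] and a JSON sidecar
#' (`<path>.json`) records the hyperparameters, input shape, kidney side and
#' training seed for inspection without deserializing the weights.
#'
#' @param net A `renalvol_unet`.
#' @param path Checkpoint file (conventionally `.rds`).
#' @param training_seed Optional seed to record in the sidecar.
#' @return `path` invisibly; `load_unet()` returns the model.
#' @export
save_unet <- function(net, path, training_seed = NULL) {
  stopifnot(inherits(net, "renalvol_unet"))
  saveRDS(net, path)
  jsonlite::write_json(
    list(hyperparameters = unclass(net$hp),
         input_shape = net$input_shape,
         side = net$side,
         trained = isTRUE(net$trained),
         training_seed = training_seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "renalvol_unet"))
  net
}

#' Predict a binary mask for one model-input image
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout) and thresholds the sigmoid output. If `out_shape` differs from the
#' model input shape the binary mask is resized back with nearest-neighbour
#' interpolation so pixel counts remain well-defined integers.
#'
#' @param net A trained `renalvol_unet`.
#' @param image 2D numeric matrix in `[0, 1]` with the network's input shape.
#' @param threshold Probability cut for foreground (default 0.5).
#' @param out_shape Optional `c(height, width)` of the returned mask.
#' @return Integer 0/1 matrix.
#' @export
predict_mask <- function(net, image, threshold = 0.5, out_shape = NULL) {
  stopifnot(inherits(net, "renalvol_unet"), is.matrix(image))
  if (!all(dim(image) == net$input_shape)) {
    stop("image shape (", paste(dim(image), collapse = "x"),
         ") does not match network input shape (",
         paste(net$input_shape, collapse = "x"),
         "); resize with normalize_and_resize() first")
  }
  x <- array(image, c(dim(image), 1L, 1L))
  p <- unet_forward(net, x, training = FALSE, keep_cache = FALSE)$p
  m <- matrix(as.integer(p[, , 1L, 1L] >= threshold), nrow(image), ncol(image))
  if (!is.null(out_shape) && !all(out_shape == dim(m))) {
    m <- resize_nearest(m, out_shape)
  }
  m
}
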