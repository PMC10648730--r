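# Neural-network primitives for the 2D U-Net.
#
# Tensors are 4D double arrays with dimensions (H, W, N, C): spatial rows,
# spatial columns, batch sample, channel. Channel last so that a tensor can be
# reshaped to an (H*W*N) x C matrix without copying permutations, turning every
# convolution into a small set of BLAS matrix multiplies.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

as_tensor <- function(m, h, w, n) {
  dim(m) <- c(h, w, n, dim(m)[2L])
  m
}

# 3x3 "same" convolution, stride 1; w: array (3, 3, Cin, Cout), b: length
# Cout. The compiled im2col+gemm path carries training; the plain-R
# shifted-gemm versions below (*_r) are kept as an independent reference for
# the test suite.
conv3x3_forward <- function(x, w, b) {
  .cpp_conv3x3_forward(x, w, b, FALSE)$y
}

# `cols` optionally carries the im2col matrix cached by the forward pass
# (external pointer), sparing its reconstruction.
conv3x3_backward <- function(x, w, dy, cols = NULL) {
  .cpp_conv3x3_backward(x, w, dy, cols)
}

conv3x3_forward_r <- function(x, w, b) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(w)[4L]
  xp <- array(0, c(h + 2L, wd + 2L, n, cin))
  xp[2:(h + 1L), 2:(wd + 1L), , ] <- x
  y <- matrix(rep(b, each = h * wd * n), h * wd * n, cout)
  for (ki in 1:3) {
    for (kj in 1:3) {
      xs <- xp[ki:(ki + h - 1L), kj:(kj + wd - 1L), , , drop = FALSE]
      y <- y + as_mat(xs) %*% matrix(w[ki, kj, , ], cin, cout)
    }
  }
  as_tensor(y, h, wd, n)
}

conv3x3_backward_r <- function(x, w, dy) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(w)[4L]
  xp <- array(0, c(h + 2L, wd + 2L, n, cin))
  xp[2:(h + 1L), 2:(wd + 1L), , ] <- x
  dym <- as_mat(dy)
  dw <- array(0, dim(w))
  # accumulate input gradient on a padded canvas, then crop
  dxp <- array(0, c(h + 2L, wd + 2L, n, cin))
  for (ki in 1:3) {
    for (kj in 1:3) {
      xs <- xp[ki:(ki + h - 1L), kj:(kj + wd - 1L), , , drop = FALSE]
      dw[ki, kj, , ] <- crossprod(as_mat(xs), dym)
      dxs <- dym %*% t(matrix(w[ki, kj, , ], cin, cout))
      dxp[ki:(ki + h - 1L), kj:(kj + wd - 1L), , ] <-
        dxp[ki:(ki + h - 1L), kj:(kj + wd - 1L), , , drop = FALSE] +
        as_tensor(dxs, h, wd, n)
    }
  }
  list(dx = dxp[2:(h + 1L), 2:(wd + 1L), , , drop = FALSE],
       dw = dw, db = colSums(dym))
}

# 1x1 convolution (the sigmoid output head uses this).
conv1x1_forward <- function(x, w, b) {
  d <- dim(x)
  y <- as_mat(x) %*% w
  y <- y + rep(b, each = nrow(y))
  as_tensor(y, d[1L], d[2L], d[3L])
}

conv1x1_backward <- function(x, w, dy) {
  d <- dim(x)
  dym <- as_mat(dy)
  xm <- as_mat(x)
  list(dx = as_tensor(dym %*% t(w), d[1L], d[2L], d[3L]),
       dw = crossprod(xm, dym), db = colSums(dym))
}

relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(y, dy) {
  # y is the *output* of the ReLU; gradient passes where y > 0
  dy * (y > 0)
}

# 2x2 max pooling, stride 2. Ties broken toward the first window element
# in (row, column) order; `which` records the winning window slot (1..4)
# for gradient routing.
maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1L]; w <- d[2L]
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  io <- seq.int(1L, h, 2L); jo <- seq.int(1L, w, 2L)
  a <- x[io, jo, , , drop = FALSE]
  b <- x[io + 1L, jo, , , drop = FALSE]
  cc <- x[io, jo + 1L, , , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  which <- array(4L, dim(y))
  which[cc >= y] <- 3L
  which[b >= y] <- 2L
  which[a >= y] <- 1L
  list(y = y, which = which)
}

maxpool_backward <- function(which, dy, h, w) {
  d <- dim(dy)
  dx <- array(0, c(h, w, d[3L], d[4L]))
  io <- seq.int(1L, h, 2L); jo <- seq.int(1L, w, 2L)
  dx[io, jo, , ] <- dy * (which == 1L)
  dx[io + 1L, jo, , ] <- dy * (which == 2L)
  dx[io, jo + 1L, , ] <- dy * (which == 3L)
  dx[io + 1L, jo + 1L, , ] <- dy * (which == 4L)
  dx
}

# 2x2 transpose convolution, stride 2: doubles both spatial dimensions.
# w: array (2, 2, Cin, Cout).
tconv2x2_forward <- function(x, w, b) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(w)[4L]
  xm <- as_mat(x)
  y <- array(0, c(2L * h, 2L * wd, n, cout))
  for (a in 0:1) {
    for (bb in 0:1) {
      y[seq.int(1L + a, 2L * h, 2L), seq.int(1L + bb, 2L * wd, 2L), , ] <-
        as_tensor(xm %*% matrix(w[a + 1L, bb + 1L, , ], cin, cout), h, wd, n)
    }
  }
  ym <- as_mat(y)
  ym <- ym + rep(b, each = nrow(ym))
  as_tensor(ym, 2L * h, 2L * wd, n)
}

tconv2x2_backward <- function(x, w, dy) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(w)[4L]
  xm <- as_mat(x)
  dw <- array(0, dim(w))
  dxm <- matrix(0, nrow(xm), cin)
  db <- numeric(cout)
  for (a in 0:1) {
    for (bb in 0:1) {
      dys <- dy[seq.int(1L + a, 2L * h, 2L), seq.int(1L + bb, 2L * wd, 2L), , ,
                drop = FALSE]
      dysm <- as_mat(dys)
      dw[a + 1L, bb + 1L, , ] <- crossprod(xm, dysm)
      dxm <- dxm + dysm %*% t(matrix(w[a + 1L, bb + 1L, , ], cin, cout))
      db <- db + colSums(dysm)
    }
  }
  list(dx = as_tensor(dxm, h, wd, n), dw = dw, db = db)
}

# Batch normalization over (H, W, N) per channel.
batchnorm_forward <- function(x, gamma, beta, running, training,
                              momentum = 0.9, eps = 1e-5) {
  xm <- as_mat(x)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- xm - rep(mu, each = m)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  d <- dim(x)
  list(y = as_tensor(y, d[1L], d[2L], d[3L]), xhat = xhat,
       inv_sd = inv_sd, running = running)
}

batchnorm_backward <- function(cache, gamma, dy) {
  d <- dim(dy)
  dym <- as_mat(dy)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  # standard batch-norm input gradient
  t1 <- dxhat - rep(colMeans(dxhat), each = m)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
  dxm <- (t1 - t2) * rep(cache$inv_sd, each = m)
  list(dx = as_tensor(dxm, d[1L], d[2L], d[3L]), dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(mask, dy) {
  if (is.null(mask)) dy else dy * mask
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary cross-entropy between predicted probabilities and a binary
# target, with the gradient taken w.r.t. the pre-sigmoid logits (numerically
# stable combined form: dL/dz = (p - t) / m).
bce_loss <- function(p, target, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_sigmoid_grad <- function(p, target) {
  (p - target) / length(p)
}

# He-normal weight initialisation for a conv kernel of given shape.
he_init <- function(shape, fan_in) {
  array(stats::rnorm(prod(shape), sd = sqrt(2 / fan_in)), shape)
}
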