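# Minimal convolutional-network engine.
#
# Images travel as (H, W, C, N) arrays. Convolutions are im2col + GEMM
# (compiled kernels in src/ops.cpp); downsampling is 2x2 mean pooling and
# upsampling nearest-neighbour, so every adjoint is exact and cheap.
# Only what the generator, discriminator and feature extractor need is
# implemented. All functions are internal.

conv_init <- function(c_in, c_out, k = 3, stride = 1L,
                      pad = as.integer((k - 1) / 2), gain = sqrt(2),
                      init = c("he", "orthogonal", "zeros")) {
  init <- match.arg(init)
  fan_in <- k * k * c_in
  W <- switch(init,
    he = matrix(rnorm(fan_in * c_out, sd = gain / sqrt(fan_in)), fan_in, c_out),
    orthogonal = {
      # Orthonormal columns when fan_in >= c_out, else orthonormal rows.
      q <- if (fan_in >= c_out)
        qr.Q(qr(matrix(rnorm(fan_in * c_out), fan_in, c_out)))
      else t(qr.Q(qr(matrix(rnorm(fan_in * c_out), c_out, fan_in))))
      q * gain
    },
    zeros = matrix(0, fan_in, c_out))
  list(W = W, b = rep(0, c_out), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       c_in = as.integer(c_in), c_out = as.integer(c_out))
}

conv_fw <- function(x, ly) {
  d <- dim(x)
  cols <- im2col_c(x, d[1], d[2], d[3], d[4], ly$k, ly$stride, ly$pad)
  Ho <- (d[1] + 2 * ly$pad - ly$k) %/% ly$stride + 1
  Wo <- (d[2] + 2 * ly$pad - ly$k) %/% ly$stride + 1
  y <- cols %*% ly$W
  if (any(ly$b != 0)) y <- sweep(y, 2, ly$b, "+")
  dim(y) <- c(Ho, Wo, d[4], ly$c_out)
  list(y = aperm(y, c(1, 2, 4, 3)), cols = cols, in_dim = d)
}

conv_bw <- function(ly, cache, dy, need_dx = TRUE) {
  dd <- dim(dy)
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(dd[1] * dd[2] * dd[4], dd[3])
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dym, ly$W)
    d <- cache$in_dim
    dx <- col2im_c(dcols, d[1], d[2], d[3], d[4], ly$k, ly$stride, ly$pad)
  }
  list(dx = dx, dW = dW, db = db)
}

lrelu_fw <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}
lrelu_bw <- function(dy, cache, slope = 0.2) {
  dy[cache$neg] <- dy[cache$neg] * slope
  dy
}

relu_fw <- function(x) { m <- x > 0; list(y = x * m, mask = m) }
relu_bw <- function(dy, cache) dy * cache$mask

# (tanh(z) + 1) / 2: bounded output in [0, 1].
tanh01_fw <- function(z) { t <- tanh(z); list(y = (t + 1) / 2, t = t) }
tanh01_bw <- function(dy, cache) dy * (1 - cache$t^2) / 2

sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

pool2_fw <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1], 2); j <- seq(1, d[2], 2)
  (x[i, j, , , drop = FALSE] + x[i + 1, j, , , drop = FALSE] +
     x[i, j + 1, , , drop = FALSE] + x[i + 1, j + 1, , , drop = FALSE]) / 4
}
pool2_bw <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  i <- seq(1, in_dim[1], 2); j <- seq(1, in_dim[2], 2)
  q <- dy / 4
  dx[i, j, , ] <- q; dx[i + 1, j, , ] <- q
  dx[i, j + 1, , ] <- q; dx[i + 1, j + 1, , ] <- q
  dx
}

up2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}
up2_bw <- function(dy) pool2_fw(dy) * 4

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- Adam over a named list of conv layers ----------------------------------

adam_init <- function(layers) {
  st <- lapply(layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
  list(t = 0L, s = st)
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(layers)) {
    g <- grads[[nm]]; s <- state$s[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state$s[[nm]] <- s
  }
  list(layers = layers, state = state)
}

sum_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$dW <- a[[nm]]$dW + b[[nm]]$dW
    a[[nm]]$db <- a[[nm]]$db + b[[nm]]$db
  }
  a
}
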