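# Conditional GAN for stain translation.
#
# The generator G is a U-Net: stride-2 convolutions halve resolution at
# each encoder level while doubling features, and the decoder mirrors
# them (1x1 channel projection + nearest-neighbour upsampling + 3x3
# convolution) with skip connections, ending in a (tanh + 1)/2 output so
# virtual H&E is bounded in [0, 1]. The discriminator D is a patch-based
# classifier built from the same stride-2 convolutions, scoring
# overlapping receptive fields of the candidate H&E concatenated with
# the conditioning FLIM input. The discriminator objective is the
# standard conditional cross-entropy (real labelled 1, synthetic 0); the
# generator is trained with the adversarial term plus an L1
# reconstruction term, and optionally a DISTS perceptual term (see
# full_objective()).

#' Build a U-Net generator
#'
#' `levels` stride-2 encoder stages with `base * 2^(l-1)` features at
#' stage `l` (the input resolution must be divisible by `2^levels`);
#' dropout after the bottleneck is active at training time and provides
#' the model's stochasticity.
#'
#' @param c_in Input channels (1 intensity, 3 IW-FLIM, 4 alpha-FLIM).
#' @param base Features at the first level.
#' @param levels Encoder depth (resolution is divided by `2^levels`).
#' @param dropout Bottleneck dropout probability at train time.
#' @param seed Integer fixing the weight initialisation.
#' @return An object of class `generator`.
#' @export
generator <- function(c_in, base = 64, levels = 8, dropout = 0.5, seed = 1) {
  stopifnot(c_in %in% c(1L, 3L, 4L), levels >= 2)
  with_seed(seed, {
    widths <- base * 2^(seq_len(levels) - 1)
    layers <- list()
    for (l in seq_len(levels))
      layers[[paste0("enc", l)]] <-
        conv_init(if (l == 1) c_in else widths[l - 1], widths[l],
                  k = 4, stride = 2, pad = 1)
    for (l in seq(levels - 1, 1)) {
      # 1x1 projection halves the deep feature stack before upsampling.
      layers[[paste0("proj", l)]] <-
        conv_init(widths[l + 1], widths[l], k = 1, pad = 0)
      layers[[paste0("dec", l)]] <- conv_init(2 * widths[l], widths[l])
    }
    layers[["out"]] <- conv_init(widths[1], 3, gain = 1)
    structure(list(layers = layers, c_in = as.integer(c_in), base = base,
                   levels = as.integer(levels), dropout = dropout,
                   seed = seed), class = "generator")
  })
}

gen_forward <- function(G, x, train = FALSE) {
  L <- G$levels
  cache <- list(enc = vector("list", L), dec = vector("list", L))
  enc_act <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    cf <- conv_fw(a, G$layers[[paste0("enc", l)]])
    af <- lrelu_fw(cf$y)
    cache$enc[[l]] <- list(conv = cf, act = af)
    enc_act[[l]] <- af$y
    a <- af$y
  }
  if (train && G$dropout > 0) {
    keep <- array(runif(length(a)) >= G$dropout, dim(a)) / (1 - G$dropout)
    cache$drop <- keep
    a <- a * keep
  }
  for (l in seq(L - 1, 1)) {
    pf <- conv_fw(a, G$layers[[paste0("proj", l)]])
    u <- up2_fw(pf$y)
    z <- cat_ch(u, enc_act[[l]])
    cf <- conv_fw(z, G$layers[[paste0("dec", l)]])
    af <- lrelu_fw(cf$y)
    cache$dec[[l]] <- list(proj = pf, conv = cf, act = af, n_up = dim(u)[3])
    a <- af$y
  }
  # Final upsample back to the input resolution.
  a <- up2_fw(a)
  cf <- conv_fw(a, G$layers[["out"]])
  tf <- tanh01_fw(cf$y)
  cache$out <- list(conv = cf, act = tf)
  list(y = tf$y, cache = cache)
}

gen_backward <- function(G, cache, dy) {
  L <- G$levels
  grads <- list()
  dz <- tanh01_bw(dy, cache$out$act)
  bo <- conv_bw(G$layers[["out"]], cache$out$conv, dz)
  grads[["out"]] <- bo[c("dW", "db")]
  da <- up2_bw(bo$dx)
  skip_grad <- vector("list", L)
  for (l in seq(1, L - 1)) {
    cc <- cache$dec[[l]]
    dzl <- lrelu_bw(da, cc$act)
    b <- conv_bw(G$layers[[paste0("dec", l)]], cc$conv, dzl)
    grads[[paste0("dec", l)]] <- b[c("dW", "db")]
    nu <- cc$n_up
    du <- b$dx[, , seq_len(nu), , drop = FALSE]
    skip_grad[[l]] <- b$dx[, , nu + seq_len(dim(b$dx)[3] - nu), , drop = FALSE]
    bp <- conv_bw(G$layers[[paste0("proj", l)]], cc$proj, up2_bw(du))
    grads[[paste0("proj", l)]] <- bp[c("dW", "db")]
    da <- bp$dx
  }
  if (!is.null(cache$drop)) da <- da * cache$drop
  for (l in seq(L, 1)) {
    if (l < L) da <- da + skip_grad[[l]]
    cc <- cache$enc[[l]]
    dzl <- lrelu_bw(da, cc$act)
    b <- conv_bw(G$layers[[paste0("enc", l)]], cc$conv, dzl,
                 need_dx = l > 1)
    grads[[paste0("enc", l)]] <- b[c("dW", "db")]
    if (l > 1) da <- b$dx
  }
  grads
}

#' Generate virtual H&E from a batch of inputs
#'
#' @param G A [generator()].
#' @param x `(H, W, C, N)` array (or `H x W x C`) in `[0, 1]`; `H`, `W`
#'   must be divisible by `2^levels`.
#' @param train Enable bottleneck dropout (training mode).
#' @return Array of the same spatial shape with 3 channels in `[0, 1]`.
#' @export
generate <- function(G, x, train = FALSE) {
  was_3d <- length(dim(x)) == 3
  if (was_3d) dim(x) <- c(dim(x), 1L)
  out <- gen_forward(G, x, train = train)$y
  if (was_3d) dim(out) <- dim(out)[1:3]
  out
}

#' Build a patch-based conditional discriminator
#'
#' Scores a grid of overlapping receptive fields of the candidate H&E
#' channel-concatenated with the conditioning input; sigmoid scores in
#' (0, 1).
#'
#' @param c_cond Channels of the conditioning stain input.
#' @param base Features of the first stage.
#' @param seed Integer fixing the initialisation.
#' @return An object of class `discriminator`.
#' @export
discriminator <- function(c_cond, base = 16, seed = 2) {
  with_seed(seed, {
    layers <- list(
      d1 = conv_init(3 + c_cond, base, k = 4, stride = 2, pad = 1),
      d2 = conv_init(base, base * 2, k = 4, stride = 2, pad = 1),
      d3 = conv_init(base * 2, 1, gain = 1))
    structure(list(layers = layers, c_cond = as.integer(c_cond),
                   base = base, seed = seed), class = "discriminator")
  })
}

# Forward to logits. Input: candidate H&E (H,W,3,N) + condition (H,W,C,N).
disc_forward <- function(D, he, cond) {
  x <- cat_ch(he, cond)
  c1 <- conv_fw(x, D$layers$d1); a1 <- lrelu_fw(c1$y)
  c2 <- conv_fw(a1$y, D$layers$d2); a2 <- lrelu_fw(c2$y)
  c3 <- conv_fw(a2$y, D$layers$d3)
  list(z = c3$y, cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3))
}

disc_backward <- function(D, cache, dz, need_dx = FALSE) {
  b3 <- conv_bw(D$layers$d3, cache$c3, dz)
  b2 <- conv_bw(D$layers$d2, cache$c2, lrelu_bw(b3$dx, cache$a2))
  b1 <- conv_bw(D$layers$d1, cache$c1, lrelu_bw(b2$dx, cache$a1),
                need_dx = need_dx)
  list(grads = list(d1 = b1[c("dW", "db")], d2 = b2[c("dW", "db")],
                    d3 = b3[c("dW", "db")]),
       dx = b1$dx)
}

#' Discriminator scores for a candidate image
#'
#' @param D A [discriminator()].
#' @param he Candidate H&E, `H x W x 3` (or batched `(H,W,3,N)`).
#' @param cond Conditioning stain input of matching spatial shape.
#' @return Grid of realism scores in `(0, 1)`.
#' @export
discriminate <- function(D, he, cond) {
  was_3d <- length(dim(he)) == 3
  if (was_3d) { dim(he) <- c(dim(he), 1L); dim(cond) <- c(dim(cond), 1L) }
  z <- disc_forward(D, he, cond)$z
  s <- sigmoid(z)
  if (was_3d) dim(s) <- dim(s)[1:3]
  s
}

#' Conditional adversarial losses
#'
#' Standard conditional-GAN cross-entropy with the real image labelled
#' 1: `loss_D = -[mean log D(h|f) + mean log(1 - D(s|f))]` and
#' `loss_G_adv = -mean log D(s|f)`, means over the score grid (and
#' batch). Scores are clipped away from 0/1 by `eps` inside the logs.
#'
#' @param D A [discriminator()].
#' @param f Conditioning stain input raster (`H x W x C` or batched).
#' @param h Real H&E raster.
#' @param s Generated H&E raster (treated as a constant inside
#'   `loss_D`).
#' @param eps Guard inside the logarithms.
#' @return List with `loss_D` and `loss_G_adv`.
#' @export
adversarial_losses <- function(D, f, h, s, eps = 1e-7) {
  p_real <- pmin(pmax(discriminate(D, h, f), eps), 1 - eps)
  p_fake <- pmin(pmax(discriminate(D, s, f), eps), 1 - eps)
  list(loss_D = -(mean(log(p_real)) + mean(log(1 - p_fake))),
       loss_G_adv = -mean(log(p_fake)))
}

#' Mean absolute (L1) reconstruction loss
#'
#' @param h,s Equal-shaped rasters.
#' @return Mean absolute difference over all pixels and channels.
#' @export
l1_loss <- function(h, s) {
  if (!all(dim(h) == dim(s)))
    stop("l1_loss: shape mismatch: ", paste(dim(h), collapse = "x"), " vs ",
         paste(dim(s), collapse = "x"))
  mean(abs(h - s))
}

#' Loss weights of the combined objective
#'
#' Defaults `alpha = 0.1` (adversarial), `beta = 1` (L1), `lambda = 5`
#' (DISTS).
#'
#' @param alpha,beta,lambda Non-negative weights, not all zero.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.1, beta = 1, lambda = 5) {
  stopifnot(alpha >= 0, beta >= 0, lambda >= 0)
  if (alpha + beta + lambda == 0) stop("all loss weights are zero")
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "loss_weights")
}

#' Combined GAN objective (adversarial + L1)
#'
#' `alpha * loss_G_adv + beta * loss_L1`; the DISTS term is added by
#' [full_objective()].
#'
#' @param loss_G_adv,loss_L1 Scalar loss components.
#' @param w A [loss_weights()].
#' @return Scalar objective.
#' @export
combine_gan_objective <- function(loss_G_adv, loss_L1, w = loss_weights()) {
  w$alpha * loss_G_adv + w$beta * loss_L1
}
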