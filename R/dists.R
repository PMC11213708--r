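# Deep image structure and texture similarity (DISTS).
#
# A feature extractor F maps an RGB image to feature-map stacks over
# stages i = 0..m, where stage 0 is the image itself. For each feature
# map, a texture term compares global means and a structure term
# compares global (co)variances; DISTS is one minus the weighted sum of
# both over all maps, with non-negative weights eta/theta summing to 1,
# so identical images score exactly 0. The loss is differentiable with
# respect to the synthetic image and so usable as a training objective.

#' Build a convolutional feature extractor
#'
#' A stack of 3x3 convolution + ReLU stages separated by 2x2 mean
#' pooling, with deterministically (orthogonally) initialised fixed
#' weights, so no pretrained download is required and results are
#' identical on every platform. Stage 0 of the extracted features is
#' always the input image.
#'
#' @param stages List with one integer vector per stage giving the
#'   output channels of each conv in that stage, e.g.
#'   `list(c(64, 64), c(128, 128))`; a plain numeric vector means one
#'   conv per stage.
#' @param seed Integer fixing the weights.
#' @param name Identifier stored on the object.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(stages = list(8, 16), seed = 17,
                              name = "conv") {
  if (is.numeric(stages)) stages <- as.list(stages)
  with_seed(seed, {
    c_prev <- 3L
    st <- lapply(stages, function(chs) {
      convs <- lapply(chs, function(co) {
        ly <- conv_init(c_prev, co, k = 3, init = "orthogonal")
        c_prev <<- as.integer(co)
        ly
      })
      list(convs = convs, activation = "relu")
    })
    structure(list(stages = st, name = name, seed = seed),
              class = "feature_extractor")
  })
}

#' VGG16-topology feature extractor
#'
#' The five-stage convolutional topology of VGG16 (64,64 / 128,128 /
#' 256x3 / 512x3 / 512x3 channels) with fixed orthogonally initialised
#' weights; the default backbone for [dists()].
#'
#' @param seed Integer fixing the weights.
#' @return A [feature_extractor()].
#' @export
vgg16_extractor <- function(seed = 17) {
  key <- paste0("vgg16_", seed)
  if (is.null(.flimstain_env[[key]])) {
    .flimstain_env[[key]] <- feature_extractor(
      list(c(64, 64), c(128, 128), c(256, 256, 256),
           c(512, 512, 512), c(512, 512, 512)),
      seed = seed, name = "vgg16")
  }
  .flimstain_env[[key]]
}

#' Tiny fixed linear extractor for exact-oracle testing
#'
#' One stage of two fixed 2x2-mean feature maps (stride 2, no
#' nonlinearity): map 1 is the 2x2 block mean over channels, map 2 a 2x2
#' block mean of the red-blue difference.
#'
#' @return A [feature_extractor()].
#' @export
tiny_extractor <- function() {
  W <- matrix(0, 2 * 2 * 3, 2)
  W[, 1] <- 1 / 12                       # block mean over 2x2x3
  W[1:4, 2] <- 1 / 8; W[9:12, 2] <- -1 / 8  # (R - B) block contrast
  ly <- list(W = W, b = c(0, 0), k = 2L, stride = 2L, pad = 0L,
             c_in = 3L, c_out = 2L)
  structure(list(stages = list(list(convs = list(ly),
                                    activation = "linear")),
                 name = "tiny", seed = NA_integer_),
            class = "feature_extractor")
}

fx_map_counts <- function(ex) {
  c(3L, vapply(ex$stages, function(st)
    st$convs[[length(st$convs)]]$c_out, integer(1)))
}

# Forward pass collecting per-stage features (stage 0 = input).
fx_forward <- function(ex, x) {
  feats <- list(x)
  caches <- vector("list", length(ex$stages))
  a <- x
  for (i in seq_along(ex$stages)) {
    st <- ex$stages[[i]]
    pc <- NULL
    if (i > 1) { pc <- dim(a); a <- pool2_fw(a) }
    convs <- vector("list", length(st$convs))
    for (k in seq_along(st$convs)) {
      cf <- conv_fw(a, st$convs[[k]])
      if (st$activation == "relu") {
        af <- relu_fw(cf$y); a <- af$y
      } else af <- NULL
      if (st$activation != "relu") a <- cf$y
      convs[[k]] <- list(conv = cf, act = af)
    }
    caches[[i]] <- list(convs = convs, pool_dim = pc)
    feats[[i + 1]] <- a
  }
  list(feats = feats, caches = caches)
}

# Backward: dfeats is a list of gradients w.r.t. each stage's features
# (stage 0 first); returns the gradient w.r.t. the input image.
fx_backward <- function(ex, caches, dfeats) {
  m <- length(ex$stages)
  g <- NULL
  for (i in seq(m, 1)) {
    st <- ex$stages[[i]]
    gi <- dfeats[[i + 1]]
    if (!is.null(g)) gi <- gi + g
    for (k in seq(length(st$convs), 1)) {
      cc <- caches[[i]]$convs[[k]]
      dz <- if (st$activation == "relu") relu_bw(gi, cc$act) else gi
      gi <- conv_bw(st$convs[[k]], cc$conv, dz)$dx
    }
    g <- if (i > 1) pool2_bw(gi, caches[[i]]$pool_dim) else gi
  }
  g + dfeats[[1]]
}

#' Texture / structure quality terms of one feature-map pair
#'
#' The texture term compares global means,
#' `(2 mu_r mu_s + c1) / (mu_r^2 + mu_s^2 + c1)`; the structure term
#' compares global (co)variances,
#' `(2 sigma_rs + c2) / (sigma_r^2 + sigma_s^2 + c2)` (population
#' moments). Both equal 1 for identical maps.
#'
#' @param r_map,s_map Equal-shaped numeric feature maps.
#' @param c1,c2 Small numeric-stability constants (default 1e-6).
#' @return Scalar in `[-1, 1]` (up to the stability constant).
#' @export
texture_term <- function(r_map, s_map, c1 = 1e-6) {
  stopifnot(all(dim(r_map) == dim(s_map)))
  mr <- mean(r_map); ms <- mean(s_map)
  (2 * mr * ms + c1) / (mr^2 + ms^2 + c1)
}

#' @rdname texture_term
#' @export
structure_term <- function(r_map, s_map, c2 = 1e-6) {
  stopifnot(all(dim(r_map) == dim(s_map)))
  mr <- mean(r_map); ms <- mean(s_map)
  srs <- mean(r_map * s_map) - mr * ms
  s2r <- mean(r_map^2) - mr^2
  s2s <- mean(s_map^2) - ms^2
  (2 * srs + c2) / (s2r + s2s + c2)
}

#' Per-map DISTS weights
#'
#' One non-negative `(eta, theta)` pair per feature map, summing to 1
#' over all maps of all stages (stage 0 included). The default is
#' uniform; a weight file trained elsewhere may be loaded with
#' [read_dists_weights()].
#'
#' @param extractor The [feature_extractor()] fixing the stage
#'   structure.
#' @param eta,theta Optional lists (one numeric vector per stage); both
#'   or neither.
#' @return An object of class `dists_weights`.
#' @export
dists_weights <- function(extractor, eta = NULL, theta = NULL) {
  nm <- fx_map_counts(extractor)
  if (is.null(eta) != is.null(theta))
    stop("supply both eta and theta, or neither")
  if (is.null(eta)) {
    tot <- 2 * sum(nm)
    eta <- lapply(nm, function(n) rep(1 / tot, n))
    theta <- eta
  }
  if (length(eta) != length(nm) ||
      any(vapply(eta, length, 1L) != nm) ||
      any(vapply(theta, length, 1L) != nm))
    stop("weight shape does not match the extractor's stage structure")
  s <- sum(unlist(eta)) + sum(unlist(theta))
  if (abs(s - 1) > 1e-9)
    stop("DISTS weights must sum to 1 (got ", format(s), ")")
  if (any(unlist(eta) < 0) || any(unlist(theta) < 0))
    stop("DISTS weights must be non-negative")
  structure(list(eta = eta, theta = theta), class = "dists_weights")
}

#' Read / write DISTS weights as JSON
#'
#' JSON object mapping stage index (as character, `"0"` upward) to
#' `{eta: [...], theta: [...]}`.
#'
#' @param path JSON file path.
#' @param extractor Extractor used to validate the stage structure.
#' @export
read_dists_weights <- function(path, extractor) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- order(as.integer(names(j)))
  dists_weights(extractor,
                eta = unname(lapply(j[idx], `[[`, "eta")),
                theta = unname(lapply(j[idx], `[[`, "theta")))
}

#' @rdname read_dists_weights
#' @param w A [dists_weights()].
#' @export
write_dists_weights <- function(w, path) {
  j <- lapply(seq_along(w$eta), function(i)
    list(eta = w$eta[[i]], theta = w$theta[[i]]))
  names(j) <- as.character(seq_along(w$eta) - 1)
  jsonlite::write_json(j, path, digits = NA)
  invisible(path)
}

as_rgb_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 1) x <- x[, , c(1, 1, 1), drop = FALSE]
  if (dim(x)[3] != 3) stop("DISTS inputs must have 1 or 3 channels")
  dim(x) <- c(dim(x), 1L)
  x
}

#' DISTS perceptual distance
#'
#' `1 - sum_ij (eta_ij T_ij + theta_ij S_ij)` over all feature maps of
#' both images; 0 for identical inputs, symmetric in its arguments.
#' With `grad = TRUE` the gradient with respect to `s` is attached as
#' `attr(, "grad_s")`.
#'
#' @param r,s Equal-shaped images (`H x W x 3`, or 2-D, replicated to
#'   RGB).
#' @param extractor A [feature_extractor()]; default the
#'   [vgg16_extractor()].
#' @param weights A [dists_weights()] matching the extractor.
#' @param c1,c2 Stability constants.
#' @param grad Also compute the gradient with respect to `s`.
#' @return Scalar distance (usually in `[0, 1]`; at most 2 when
#'   structure terms go negative).
#' @export
dists <- function(r, s, extractor = vgg16_extractor(),
                  weights = dists_weights(extractor),
                  c1 = 1e-6, c2 = 1e-6, grad = FALSE) {
  if (!all(dim(r) == dim(s))) stop("DISTS inputs differ in shape")
  rb <- as_rgb_batch(r); sb <- as_rgb_batch(s)
  res <- dists_core(rb, sb, extractor, weights, c1, c2, grad)
  out <- res$values[1]
  if (grad) {
    g <- res$grad
    if (length(dim(s)) == 3 && dim(s)[3] == 3) {
      dim(g) <- dim(g)[1:3]
    } else {
      # 1-channel input was replicated to RGB: channel grads add up.
      gsum <- g[, , 1, 1] + g[, , 2, 1] + g[, , 3, 1]
      g <- if (is.matrix(s)) gsum else array(gsum, dim(s))
    }
    attr(out, "grad_s") <- g
  }
  out
}

# Batched DISTS over (H, W, 3, N) stacks: per-image values and, when
# requested, the gradient of sum(values) with respect to s.
dists_core <- function(rb, sb, extractor, weights, c1 = 1e-6, c2 = 1e-6,
                       grad = FALSE) {
  nm <- fx_map_counts(extractor)
  if (length(weights$eta) != length(nm) ||
      any(vapply(weights$eta, length, 1L) != nm))
    stop("weight shape does not match the extractor's stage structure")
  fr <- fx_forward(extractor, rb)
  fs <- fx_forward(extractor, sb)
  nbatch <- dim(rb)[4]
  vals <- rep(1, nbatch)
  dfeats <- if (grad) vector("list", length(nm)) else NULL
  for (i in seq_along(nm)) {
    Fr <- fr$feats[[i]]; Fs <- fs$feats[[i]]
    d <- dim(Fr); np <- d[1] * d[2]; ncn <- d[3] * d[4]
    Mr <- matrix(Fr, np, ncn); Ms <- matrix(Fs, np, ncn)
    mr <- colMeans(Mr); ms <- colMeans(Ms)
    srs <- colMeans(Mr * Ms) - mr * ms
    s2r <- colMeans(Mr^2) - mr^2
    s2s <- colMeans(Ms^2) - ms^2
    numT <- 2 * mr * ms + c1; denT <- mr^2 + ms^2 + c1
    numS <- 2 * srs + c2;     denS <- s2r + s2s + c2
    eta <- rep(weights$eta[[i]], times = d[4])
    theta <- rep(weights$theta[[i]], times = d[4])
    contrib <- eta * numT / denT + theta * numS / denS
    vals <- vals - colSums(matrix(contrib, d[3], d[4]))
    if (grad) {
      dT_dms <- (2 * mr * denT - numT * 2 * ms) / denT^2
      dS_dsrs <- 2 / denS
      dS_ds2s <- -numS / denS^2
      a0 <- eta * dT_dms / np - theta * (dS_dsrs * mr / np +
                                           dS_ds2s * 2 * ms / np)
      aR <- theta * dS_dsrs / np
      aS <- theta * dS_ds2s * 2 / np
      dmap <- -(matrix(a0, np, ncn, byrow = TRUE) +
                  Mr * matrix(aR, np, ncn, byrow = TRUE) +
                  Ms * matrix(aS, np, ncn, byrow = TRUE))
      dfeats[[i]] <- array(dmap, d)
    }
  }
  g <- if (grad) fx_backward(extractor, fs$caches, dfeats) else NULL
  list(values = vals, grad = g)
}

#' Full training objective
#'
#' `alpha * loss_G_adv + beta * loss_L1 + lambda * dists_value`.
#'
#' @param loss_G_adv,loss_L1,dists_value Scalar components.
#' @param w A [loss_weights()].
#' @return Scalar objective.
#' @export
full_objective <- function(loss_G_adv, loss_L1, dists_value,
                           w = loss_weights()) {
  w$alpha * loss_G_adv + w$beta * loss_L1 + w$lambda * dists_value
}
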