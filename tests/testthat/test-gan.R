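test_that("adversarial losses follow the conditional cross-entropy form", {
  # closed form at D = 0.5 everywhere: a zero-weight discriminator with
  # zero-logit output scores 0.5 after the sigmoid
  D <- discriminator(3, base = 4, seed = 1)
  for (nm in names(D$layers)) {
    D$layers[[nm]]$W[] <- 0
    D$layers[[nm]]$b[] <- 0
  }
  f <- fixture_rgb(1, 16); h <- fixture_rgb(2, 16); s <- fixture_rgb(3, 16)
  expect_equal(as.vector(discriminate(D, h, f))[1], 0.5)
  losses <- adversarial_losses(D, f, h, s)
  expect_equal(losses$loss_D, 2 * log(2), tolerance = 1e-9)
  expect_equal(losses$loss_G_adv, log(2), tolerance = 1e-9)
  # losses are finite for any scores in (0, 1)
  D2 <- discriminator(3, base = 4, seed = 7)
  l2 <- adversarial_losses(D2, f, h, s)
  expect_true(is.finite(l2$loss_D) && is.finite(l2$loss_G_adv))
  expect_gt(l2$loss_D, 0)
})

test_that("L1 loss is the symmetric mean absolute difference", {
  h <- fixture_rgb(4, 16)
  expect_equal(l1_loss(h, h), 0)
  expect_equal(l1_loss(h, pmin(h + 0.1, 1.1)), 0.1, tolerance = 1e-12)
  s <- fixture_rgb(5, 16)
  expect_equal(l1_loss(h, s), l1_loss(s, h))
  expect_error(l1_loss(h, s[1:8, , ]), "shape mismatch")
})

test_that("objective weighting reduces correctly at zero weights", {
  expect_equal(combine_gan_objective(0.6931, 0.2, loss_weights(0.1, 1, 5)),
               0.26931, tolerance = 1e-9)
  expect_equal(combine_gan_objective(3, 0.2, loss_weights(0, 1, 0)), 0.2)
  expect_equal(combine_gan_objective(3, 0.2, loss_weights(1, 0, 0)), 3)
  expect_equal(full_objective(0.6931, 0.2, 0.05, loss_weights(0.1, 1, 5)),
               0.51931, tolerance = 1e-9)
  expect_equal(full_objective(0.6931, 0.2, 0.7, loss_weights(0.1, 1, 0)),
               combine_gan_objective(0.6931, 0.2, loss_weights(0.1, 1, 5)))
  expect_error(loss_weights(0, 0, 0), "zero")
})

test_that("generator output is bounded in [0, 1] at the input shape", {
  G <- generator(3, base = 8, levels = 3, seed = 5)
  x <- fixture_rgb(6, 32)
  y <- generate(G, x)
  expect_equal(dim(y), c(32, 32, 3))
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  # batched input
  xb <- array(x, c(32, 32, 3, 2))
  yb <- generate(G, xb)
  expect_equal(dim(yb), c(32, 32, 3, 2))
  expect_equal(yb[, , , 1], y)
})

test_that("generator and discriminator gradients match finite differences", {
  withr::local_seed(8)
  G <- generator(3, base = 4, levels = 2, dropout = 0, seed = 9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  fw <- flimstain:::gen_forward(G, x)
  loss <- function(s) mean(abs(s - y))
  gr <- flimstain:::gen_backward(G, fw$cache, sign(fw$y - y) / length(fw$y))
  eps <- 1e-6
  for (nm in c("enc1", "enc2", "proj1", "dec1", "out")) {
    G2 <- G
    G2$layers[[nm]]$W[2, 1] <- G2$layers[[nm]]$W[2, 1] + eps
    fd <- (loss(flimstain:::gen_forward(G2, x)$y) - loss(fw$y)) / eps
    expect_equal(gr[[nm]]$dW[2, 1], fd, tolerance = 1e-4)
  }
  D <- discriminator(3, base = 4, seed = 3)
  ff <- flimstain:::disc_forward(D, y, x)
  dl <- function(z) mean(flimstain:::softplus(z))
  bb <- flimstain:::disc_backward(D, ff$cache,
                                  flimstain:::sigmoid(ff$z) / length(ff$z),
                                  need_dx = TRUE)
  for (nm in c("d1", "d2", "d3")) {
    D2 <- D
    D2$layers[[nm]]$W[3, 1] <- D2$layers[[nm]]$W[3, 1] + eps
    fd <- (dl(flimstain:::disc_forward(D2, y, x)$z) - dl(ff$z)) / eps
    expect_equal(bb$grads[[nm]]$dW[3, 1], fd, tolerance = 1e-4)
  }
})

test_that("training a tiny generator on one pair drives L1 below its start", {
  # overfit sanity: pure L1 objective (alpha = 0, lambda = 0)
  fld <- fixture_field(31, 64)
  si <- make_iw_flim(fld)
  he <- fixture_phantom(31, 64)$he
  pair <- list(x = si$pixels[1:32, 1:32, , drop = FALSE],
               y = he[1:32, 1:32, , drop = FALSE])
  cfg <- pipeline_config(profile = "desk", seed = 4, epochs = 50,
                         alpha = 0, lambda = 0, batch_size = 1,
                         gen_base = 8, augment_flip = FALSE,
                         augment_rotate = FALSE, gen_dropout = 0)
  ck <- train_gan(list(pair), cfg)
  expect_lt(ck$log$l1[50], ck$log$l1[1])
  expect_lt(ck$log$l1[50], 0.05)
})

test_that("training is reproducible and resumable", {
  pairs <- phantom_patch_pairs(1, c(64, 64), patch = 32, seed = 40,
                               max_background = 1)
  cfg <- pipeline_config(profile = "desk", seed = 6, epochs = 2,
                         gen_base = 8, disc_base = 8, batch_size = 2)
  a <- train_gan(pairs, cfg)
  b <- train_gan(pairs, cfg)
  expect_identical(a$G$layers, b$G$layers)
  expect_identical(a$log, b$log)
  # fine-tuning continues the epoch counter and accepts matching channels
  c2 <- train_gan(pairs, pipeline_config(profile = "desk", seed = 6,
                                         epochs = 1, gen_base = 8,
                                         disc_base = 8, batch_size = 2),
                  resume = a)
  expect_equal(c2$header$epoch, 3)
  bad <- list(header = list(c_in = 4))
  expect_error(train_gan(pairs, cfg, resume = bad), "channels")
})
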