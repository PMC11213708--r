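# Pipeline orchestration: configuration, training loop, whole-field
# inference, and the command-style entry points the CLI script wraps.

#' Pipeline configuration
#'
#' Defaults follow the reference training recipe: Adam with beta1 0.5 /
#' beta2 0.999, learning rate 1e-4 divided by 10 every 60 epochs, 300
#' epochs, loss weights alpha 0.1 / beta 1 / lambda 5, 256x256 patches,
#' horizontal-flip and +/-15 degree rotation augmentation. The `"desk"`
#' profile swaps in a configuration sized for a single CPU: 64x64
#' patches, a 3-level U-Net with 16 base features, a small feature
#' extractor, 20 epochs and a learning rate of 2e-3 suited to the small
#' network.
#'
#' @param ... Named overrides of any default field.
#' @param profile `"full"` (reference recipe) or `"desk"` (CPU-sized).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., profile = c("full", "desk")) {
  profile <- match.arg(profile)
  cfg <- list(
    raw_dir = NULL, out_dir = NULL,
    format_tag = "IW_FLIM",
    colormap = "flim_default",
    clamp_intensity = 2000, clamp_lifetime = 5,
    lifetime_range = c(1, 5),
    he_pixel_size = 0.22, flim_pixel_size = 0.455,
    assume_registered = FALSE,
    patch = 256L, stride_train = 128L, stride_eval = 256L,
    background_threshold = 0.05, max_background = 0.75,
    alpha = 0.1, beta = 1, lambda = 5,
    adam_beta1 = 0.5, adam_beta2 = 0.999,
    lr_init = 1e-4, lr_decay_factor = 10, lr_decay_epochs = 60,
    epochs = 300L, batch_size = 4L,
    gen_base = 64L, gen_levels = 8L, disc_base = 64L, gen_dropout = 0.5,
    extractor_stages = "vgg16",
    augment_flip = TRUE, augment_rotate = TRUE, rotate_deg = 15,
    seed = 1L, profile = profile)
  if (profile == "desk")
    cfg <- modifyList(cfg, list(
      patch = 64L, stride_train = 64L, stride_eval = 64L,
      epochs = 20L, lr_init = 2e-3, batch_size = 8L,
      gen_base = 16L, gen_levels = 3L, disc_base = 16L,
      extractor_stages = c(8, 16),
      he_pixel_size = 0.455, assume_registered = TRUE))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$patch > 0, cfg$epochs >= 1, cfg$lr_init > 0,
            cfg$batch_size >= 1, cfg$max_background >= 0,
            cfg$max_background <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr_init / factor^floor((epoch - 1) / decay_epochs)`,
#' i.e. 1e-4, 1e-5 from epoch 61, 1e-6 from epoch 121 under the
#' defaults.
#'
#' @param config A [pipeline_config()].
#' @param epoch 1-based epoch number.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr_init /
    config$lr_decay_factor^floor((epoch - 1) / config$lr_decay_epochs)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips to an equal object.
#'
#' @param config A [pipeline_config()]; `path` a YAML file.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  prof <- v$profile %||% "full"
  v$profile <- NULL
  do.call(pipeline_config, c(v, list(profile = prof)))
}

config_extractor <- function(config) {
  if (identical(config$extractor_stages, "vgg16")) vgg16_extractor()
  else feature_extractor(as.list(config$extractor_stages))
}

config_colormap <- function(config) {
  if (identical(config$colormap, "flim_default")) flim_colormap()
  else read_colormap_csv(config$colormap)
}

#' Build the configured network input for a field
#'
#' @param field A clamped [flim_field()].
#' @param config A [pipeline_config()].
#' @param ctx Normalisation bounds.
#' @return A [stain_input()].
#' @export
build_stain_input <- function(field, config, ctx = norm_ctx()) {
  cm <- config_colormap(config)
  switch(config$format_tag,
         INTENSITY = make_intensity_input(field, ctx),
         ALPHA_FLIM = make_alpha_flim(field, ctx, cm, config$lifetime_range),
         IW_FLIM = make_iw_flim(field, ctx, cm, config$lifetime_range),
         stop("unknown format_tag: ", config$format_tag))
}

format_fill <- function(format_tag) {
  if (format_tag == "INTENSITY") 1 else 0
}

# Random flip / small-rotation augmentation of one (input, target) pair.
augment_pair <- function(x, y, config) {
  if (config$augment_flip && runif(1) < 0.5) {
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    y <- y[, rev(seq_len(dim(y)[2])), , drop = FALSE]
  }
  if (config$augment_rotate) {
    ang <- runif(1, -config$rotate_deg, config$rotate_deg)
    ctr <- (dim(x)[1:2] - 1) / 2
    t <- affine_from_params(angle = ang, centre = ctr)
    x <- apply_affine(x, t, dim(x)[1:2], fill = format_fill(config$format_tag))
    y <- apply_affine(y, t, dim(y)[1:2], fill = 1)
  }
  list(x = x, y = y)
}

stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

# One simultaneous optimisation step on a batch: D and G gradients are
# both taken at the current parameters (one fake pass serves both), then
# applied together.
gan_step <- function(st, x, y, config, extractor, dw, w, lr) {
  gf <- gen_forward(st$G, x, train = TRUE)
  s <- gf$y
  nb <- dim(x)[4]
  # --- discriminator gradients (synthetic treated as constant)
  fr <- disc_forward(st$D, y, x)
  ff <- disc_forward(st$D, s, x)
  nsc <- length(fr$z)
  loss_D <- mean(softplus(-fr$z)) + mean(softplus(ff$z))
  dzr <- -sigmoid(-fr$z) / nsc
  dzf <- sigmoid(ff$z) / nsc
  gr <- disc_backward(st$D, fr$cache, dzr * w$alpha)
  gfk <- disc_backward(st$D, ff$cache, dzf * w$alpha)
  # --- generator gradients through the same fake pass
  loss_adv <- mean(softplus(-ff$z))
  dz <- -sigmoid(-ff$z) / nsc
  badv <- disc_backward(st$D, ff$cache, dz * w$alpha, need_dx = TRUE)
  ds <- badv$dx[, , 1:3, , drop = FALSE]
  loss_l1 <- mean(abs(s - y))
  ds <- ds + w$beta * sign(s - y) / length(s)
  loss_dists <- 0
  if (w$lambda > 0) {
    dv <- dists_core(y, s, extractor, dw, grad = TRUE)
    loss_dists <- mean(dv$values)
    ds <- ds + (w$lambda / nb) * dv$grad
  }
  gg <- gen_backward(st$G, gf$cache, ds)
  upd <- adam_step(st$D$layers, sum_grads(gr$grads, gfk$grads), st$adamD,
                   lr, config$adam_beta1, config$adam_beta2)
  st$D$layers <- upd$layers; st$adamD <- upd$state
  upd <- adam_step(st$G$layers, gg, st$adamG, lr,
                   config$adam_beta1, config$adam_beta2)
  st$G$layers <- upd$layers; st$adamG <- upd$state
  c(adv = loss_adv, l1 = loss_l1, dists = loss_dists, d = loss_D,
    total = w$alpha * loss_adv + w$beta * loss_l1 + w$lambda * loss_dists)
}

#' Train the stain-translation GAN
#'
#' Alternating Adam updates of discriminator and generator under the
#' combined adversarial + L1 + DISTS objective, with the configured
#' step-decay learning-rate schedule and flip/rotation augmentation.
#' Fully deterministic given `config$seed`. Pass a previous checkpoint
#' to fine-tune (transfer learning) instead of initialising fresh
#' weights.
#'
#' @param pairs List of training pairs: `patch_pair`s from
#'   [extract_patches()] or plain `list(x = , y = )` with `x` an
#'   `H x W x C` input and `y` the matching `H x W x 3` H&E target.
#' @param config A [pipeline_config()].
#' @param resume Optional checkpoint to fine-tune from.
#' @return A checkpoint: list with `G`, `D`, `header` (format, channel
#'   count, architecture, epochs trained) and per-epoch `log`
#'   data.frame.
#' @export
train_gan <- function(pairs, config = pipeline_config(profile = "desk"),
                      resume = NULL) {
  stopifnot(length(pairs) >= 1)
  if (any(vapply(pairs, is.null, logical(1))))
    stop("training pairs contain NULL entries")
  get_x <- function(p) p$x %||% p$input_patch
  get_y <- function(p) p$y %||% p$target_patch
  c_in <- dim(get_x(pairs[[1]]))[3]
  if (!is.null(resume)) {
    if (resume$header$c_in != c_in)
      stop("checkpoint expects ", resume$header$c_in,
           " input channels, data has ", c_in)
    G <- resume$G; D <- resume$D
    epoch0 <- resume$header$epoch
  } else {
    G <- generator(c_in, base = config$gen_base, levels = config$gen_levels,
                   dropout = config$gen_dropout, seed = config$seed + 101L)
    D <- discriminator(c_in, base = config$disc_base,
                       seed = config$seed + 202L)
    epoch0 <- 0L
  }
  extractor <- config_extractor(config)
  dw <- dists_weights(extractor)
  w <- loss_weights(config$alpha, config$beta, config$lambda)
  st <- new.env(parent = emptyenv())
  st$G <- G; st$D <- D
  st$adamG <- adam_init(G$layers); st$adamD <- adam_init(D$layers)
  n <- length(pairs)
  logs <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch0 + ep)
      ord <- sample(n)
      comp <- c(adv = 0, l1 = 0, dists = 0, d = 0, total = 0)
      nb <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        xs <- list(); ys <- list()
        for (i in seq_along(idx)) {
          p <- pairs[[idx[i]]]
          a <- augment_pair(get_x(p), get_y(p), config)
          xs[[i]] <- a$x; ys[[i]] <- a$y
        }
        losses <- gan_step(st, stack_batch(xs), stack_batch(ys),
                           config, extractor, dw, w, lr)
        comp <- comp + losses
        nb <- nb + 1
      }
      logs[[ep]] <- data.frame(epoch = epoch0 + ep, lr = lr,
                               t(comp / nb))
      log_event("train", epoch = epoch0 + ep,
                total = round(comp[["total"]] / nb, 4))
    }
  })
  log <- do.call(rbind, logs)
  if (!is.null(resume)) log <- rbind(resume$log, log)
  list(G = st$G, D = st$D,
       header = list(format_tag = config$format_tag, c_in = c_in,
                     gen_base = config$gen_base,
                     gen_levels = config$gen_levels,
                     disc_base = config$disc_base,
                     epoch = epoch0 + config$epochs,
                     seed = config$seed),
       log = log)
}

#' Save / load a checkpoint
#'
#' Single-file archive of generator and discriminator parameters with a
#' JSON-serialisable header (format tag, channels, architecture,
#' epochs).
#'
#' @param ckpt Checkpoint from [train_gan()]; `path` an `.rds` file.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Whole-field virtual staining
#'
#' Runs the generator on an arbitrarily sized field without patch
#' seams: the input is padded to the next multiple of the network's
#' downsampling factor, inferred in one pass, and cropped back.
#'
#' @param ckpt Checkpoint (or bare [generator()]).
#' @param input A [stain_input()] (or H x W x C array) for the whole
#'   field.
#' @return `H x W x 3` virtual H&E raster in `[0, 1]`.
#' @export
stain_field <- function(ckpt, input) {
  G <- if (inherits(ckpt, "generator")) ckpt else ckpt$G
  px <- if (inherits(input, "stain_input")) input$pixels else input
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  if (dim(px)[3] != G$c_in)
    stop("checkpoint expects ", G$c_in, " channels, field has ",
         dim(px)[3])
  m <- 2^G$levels
  d <- dim(px)
  Hp <- ceiling(d[1] / m) * m; Wp <- ceiling(d[2] / m) * m
  if (Hp != d[1] || Wp != d[2]) {
    pad <- array(0, c(Hp, Wp, d[3]))
    pad[seq_len(d[1]), seq_len(d[2]), ] <- px
    if (Hp > d[1])  # replicate edge rows/cols to avoid border artefacts
      pad[(d[1] + 1):Hp, seq_len(d[2]), ] <-
        px[rep(d[1], Hp - d[1]), , , drop = FALSE]
    if (Wp > d[2])
      pad[, (d[2] + 1):Wp, ] <- pad[, rep(d[2], Wp - d[2]), , drop = FALSE]
    px <- pad
  }
  out <- generate(G, px)
  out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

# ---- command-style entry points --------------------------------------------

list_fields <- function(raw_dir) {
  f <- list.files(raw_dir, pattern = "_intensity\\.tif+$", full.names = TRUE)
  if (length(f) == 0) stop("no '*_intensity.tif' rasters found in ", raw_dir)
  sub("_intensity\\.tif+$", "", basename(f))
}

read_raw_field <- function(raw_dir, id, config) {
  field <- read_flim_field(file.path(raw_dir, paste0(id, "_intensity.tif")),
                           file.path(raw_dir, paste0(id, "_lifetime.tif")),
                           field_id = id)
  he_path <- file.path(raw_dir, paste0(id, "_he.png"))
  if (!file.exists(he_path)) stop("missing H&E raster: ", he_path)
  he <- png::readPNG(he_path)
  if (length(dim(he)) == 3 && dim(he)[3] > 3) he <- he[, , 1:3]
  list(field = clamp_flim(field, config$clamp_intensity,
                          config$clamp_lifetime), he = he)
}

#' Preprocess raw fields into a patch dataset
#'
#' For every field under `config$raw_dir` (layout of
#' [write_phantom()]): clamp, build the configured network input,
#' bicubically downsample the H&E to the FLIM grid, co-register via
#' affine mutual-information registration (skipped when
#' `assume_registered`), filter background patches and write paired
#' PNGs plus a `manifest.tsv` under `config$out_dir`.
#'
#' @param config A [pipeline_config()] with `raw_dir` and `out_dir`.
#' @return Invisibly, the manifest data.frame.
#' @export
cmd_preprocess <- function(config) {
  stopifnot(!is.null(config$raw_dir), !is.null(config$out_dir))
  ids <- list_fields(config$raw_dir)
  pdir <- file.path(config$out_dir, "patches")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  fields <- lapply(ids, read_raw_field, raw_dir = config$raw_dir,
                   config = config)
  ctx <- ctx_from_fields(lapply(fields, `[[`, "field"))
  rows <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    fld <- fields[[k]]$field
    he <- fields[[k]]$he
    if (config$he_pixel_size != config$flim_pixel_size)
      he <- downsample_he(he, config$he_pixel_size, config$flim_pixel_size)
    if (!config$assume_registered) {
      mov <- prepare_he_for_registration(he)
      fix <- 1 - normalise_intensity(fld, ctx)
      t <- estimate_affine(mov, fix)
      he <- apply_affine(he, t, dim(fld$intensity), fill = 1)
      write_affine_json(t, file.path(config$out_dir,
                                     paste0(id, "_affine.json")))
    } else if (!all(dim(he)[1:2] == dim(fld$intensity))) {
      stop("field ", id, ": H&E and FLIM grids differ but ",
           "assume_registered is set")
    }
    si <- build_stain_input(fld, config, ctx)
    bg <- background_mask(fld, ctx, config$background_threshold)
    patches <- extract_patches(si, he, bg, config$patch,
                               config$stride_train, config$max_background)
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      stem <- sprintf("%s_r%04d_c%04d", id, p$origin[1], p$origin[2])
      inp <- file.path(pdir, paste0(stem, "_in.png"))
      tgp <- file.path(pdir, paste0(stem, "_he.png"))
      ip <- p$input_patch
      if (dim(ip)[3] == 1) dim(ip) <- dim(ip)[1:2]
      png::writePNG(ip, inp)
      png::writePNG(p$target_patch, tgp)
      rows[[length(rows) + 1]] <- data.frame(
        field_id = id, origin_row = p$origin[1], origin_col = p$origin[2],
        background_fraction = p$background_fraction,
        input_png = basename(inp), target_png = basename(tgp),
        stringsAsFactors = FALSE)
    }
    log_event("preprocess", field = id, kept = length(patches),
              dropped = attr(patches, "n_dropped"))
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

read_patch_dataset <- function(config) {
  man <- read.csv(file.path(config$out_dir, "manifest.tsv"), sep = "\t")
  pdir <- file.path(config$out_dir, "patches")
  lapply(seq_len(nrow(man)), function(i) {
    x <- png::readPNG(file.path(pdir, man$input_png[i]))
    if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
    list(x = x, y = png::readPNG(file.path(pdir, man$target_png[i])),
         field_id = man$field_id[i])
  })
}

#' Train from a preprocessed patch dataset on disk
#'
#' @param config A [pipeline_config()].
#' @param resume Optional checkpoint path to fine-tune from.
#' @return The checkpoint (saved to `out_dir/checkpoint.rds`).
#' @export
cmd_train <- function(config, resume = NULL) {
  pairs <- read_patch_dataset(config)
  ck <- train_gan(pairs, config,
                  resume = if (!is.null(resume)) load_checkpoint(resume))
  save_checkpoint(ck, file.path(config$out_dir, "checkpoint.rds"))
  write.csv(ck$log, file.path(config$out_dir, "loss_log.csv"),
            row.names = FALSE)
  invisible(ck)
}

#' Stain one whole field with a trained checkpoint
#'
#' @param config A [pipeline_config()].
#' @param checkpoint Checkpoint object or `.rds` path.
#' @param field_id Field identifier under `config$raw_dir`.
#' @return The virtual H&E raster (also written to
#'   `out_dir/<id>_virtual.png`).
#' @export
cmd_stain <- function(config, checkpoint, field_id) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (checkpoint$header$format_tag != config$format_tag)
    stop("checkpoint was trained on ", checkpoint$header$format_tag,
         ", config requests ", config$format_tag)
  fld <- read_raw_field(config$raw_dir, field_id, config)$field
  si <- build_stain_input(fld, config)
  out <- stain_field(checkpoint, si)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(out, file.path(config$out_dir,
                               paste0(field_id, "_virtual.png")))
  invisible(out)
}

#' Evaluate virtual against true staining
#'
#' Pairs same-named PNGs in two directories and writes the metric grid.
#'
#' @param config A [pipeline_config()].
#' @param virtual_dir,true_dir Directories of matching PNGs.
#' @return The [metric_report()].
#' @export
cmd_evaluate <- function(config, virtual_dir, true_dir) {
  vn <- sort(list.files(virtual_dir, pattern = "\\.png$"))
  tn <- sort(list.files(true_dir, pattern = "\\.png$"))
  if (!identical(gsub("_virtual", "", vn), gsub("_he", "", tn)))
    stop("virtual and true field sets do not match")
  virt <- lapply(file.path(virtual_dir, vn), png::readPNG)
  tru <- lapply(file.path(true_dir, tn), png::readPNG)
  rep <- metric_report(virt, tru, config$format_tag,
                       tools::file_path_sans_ext(vn))
  write_metric_report(rep,
                      file.path(config$out_dir, "metrics.tsv"),
                      file.path(config$out_dir, "metrics.json"))
  rep
}

#' Extract lifetime signatures for one annotated field
#'
#' @param config A [pipeline_config()].
#' @param field_id Field identifier under `config$raw_dir` (expects the
#'   `_annot.tif` / `_labels.json` companions).
#' @return The signature table (written to
#'   `out_dir/<id>_signatures.tsv`).
#' @export
cmd_signatures <- function(config, field_id) {
  fld <- read_raw_field(config$raw_dir, field_id, config)$field
  annot <- read_cell_annotation(
    file.path(config$raw_dir, paste0(field_id, "_annot.tif")),
    file.path(config$raw_dir, paste0(field_id, "_labels.json")))
  sig <- summarise_cell_types(fld, annot)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signatures(sig,
                   file.path(config$out_dir,
                             paste0(field_id, "_signatures.tsv")))
  sig
}

#' Generate phantom fields in the raw-data layout
#'
#' @param config A [pipeline_config()] (`raw_dir` is the destination).
#' @param n_fields Number of phantom fields.
#' @param image_size `(H, W)` per field.
#' @return Invisibly, the field ids written.
#' @export
cmd_phantom <- function(config, n_fields = 2, image_size = c(256, 256)) {
  stopifnot(!is.null(config$raw_dir))
  ids <- character(n_fields)
  for (i in seq_len(n_fields)) {
    sp <- phantom_spec(image_size = image_size,
                       pixel_size = config$flim_pixel_size,
                       seed = config$seed + i - 1L)
    ids[i] <- write_phantom(generate_phantom(sp), config$raw_dir)
  }
  invisible(ids)
}
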