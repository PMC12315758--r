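# Training harness: one-cycle super-convergence learning-rate schedule,
# AdamW, per-variant loss selection, the noise regimes, optional two-stage
# refinement (a frozen first-stage model preprocesses the noisy input),
# and checkpointing.

#' One-cycle learning-rate schedule parameters
#'
#' @param max_lr peak learning rate (0.01).
#' @param pct_start fraction of steps spent ramping up (0.075).
#' @param div_factor initial lr is `max_lr / div_factor` (10).
#' @param final_div_factor final lr is the initial lr divided by this (100).
#' @export
one_cycle_schedule <- function(max_lr = 0.01, pct_start = 0.075,
                               div_factor = 10, final_div_factor = 100) {
  stopifnot(max_lr > 0, pct_start > 0, pct_start < 1,
            div_factor >= 1, final_div_factor >= 1)
  structure(list(max_lr = max_lr, pct_start = pct_start,
                 div_factor = div_factor,
                 final_div_factor = final_div_factor),
            class = "one_cycle_schedule")
}

#' One-cycle learning rate at a given step
#'
#' Cosine ramp from `max_lr / div_factor` to `max_lr` over the first
#' `pct_start` fraction of steps, then cosine annealing down to
#' `(max_lr / div_factor) / final_div_factor`.
#' @param step 0-based step, `0 <= step < total_steps`.
#' @param total_steps total steps in the cycle (`>= 2`).
#' @param schedule a [one_cycle_schedule()].
#' @export
one_cycle_lr <- function(step, total_steps, schedule = one_cycle_schedule()) {
  if (total_steps < 2) stop("total_steps must be at least 2")
  stopifnot(all(step >= 0), all(step < total_steps))
  lo <- schedule$max_lr / schedule$div_factor
  fin <- lo / schedule$final_div_factor
  warm <- max(1, round(schedule$pct_start * total_steps))
  ramp <- function(s) lo + (schedule$max_lr - lo) * (1 - cos(pi * s / warm)) / 2
  anneal <- function(s) {
    t <- (s - warm) / max(1, (total_steps - 1 - warm))
    fin + (schedule$max_lr - fin) * (1 + cos(pi * t)) / 2
  }
  ifelse(step < warm, ramp(step), anneal(step))
}

# Cycled beta1 for AdamW: high at the ends of the cycle, low at the lr
# peak (0.95 -> 0.85 -> 0.95), following the momentum-cycling convention.
one_cycle_beta1 <- function(step, total_steps, schedule) {
  lr <- one_cycle_lr(step, total_steps, schedule)
  lo <- schedule$max_lr / schedule$div_factor
  s <- (lr - lo) / (schedule$max_lr - lo)
  0.95 - 0.10 * min(max(s, 0), 1)
}

#' Training configuration
#'
#' Variants: `base_feat` (deep-feature L1 loss), `base_lpips` (LPIPS-style
#' L2 feature loss), `light` / `light_doubling` (long-training
#' configurations without/with filter doubling), the refinement stages
#' `refine_low` and `refine_high` (stationary low/high noise on top of a
#' frozen first-stage model, fixed lr 1e-6), and the comparators
#' `unet_vinn` and `mcdncnn`.
#'
#' @param variant one of the above.
#' @param loss "mae", "mse", "feature_loss_l1" or "lpips_like" (default per
#'   variant).
#' @param epochs training epochs.
#' @param batch_size slabs per optimization step (default 2).
#' @param schedule a [one_cycle_schedule()], or the string "fixed" for the
#'   refinement stages' fixed learning rate.
#' @param fixed_lr learning rate when `schedule == "fixed"` (1e-6).
#' @param beta1,beta2 AdamW moment coefficients (0.9, 0.99).
#' @param weight_decay AdamW decoupled weight decay (0.01); the candidate
#'   weights lambda are excluded from decay.
#' @param mixed_precision emulate reduced-precision activations (values
#'   rounded to single precision in the forward pass).
#' @param seed global seed; per-sample noise seeds derive from
#'   (seed, epoch, sample).
#' @param regime a [noise_regime()] (default per variant).
#' @param steps_per_epoch optimization steps per epoch.
#' @param crop_size optional square crop (pixels) of training slabs.
#' @param zero_noise_frac fraction of training samples drawn with sigma
#'   exactly 0; seeing noise-free inputs during training is what keeps the
#'   trained model close to the identity on clean data.
#' @param augment an [augment_config()] (flips, rotations, inSA).
#' @export
train_config <- function(variant = c("base_feat", "base_lpips", "light",
                                     "light_doubling", "refine_low",
                                     "refine_high", "unet_vinn", "mcdncnn"),
                         loss = NULL, epochs = 2L, batch_size = 2L,
                         schedule = NULL, fixed_lr = 1e-6,
                         beta1 = 0.9, beta2 = 0.99, weight_decay = 0.01,
                         mixed_precision = FALSE, seed = 0L, regime = NULL,
                         steps_per_epoch = 100L, crop_size = NULL,
                         zero_noise_frac = 0.125,
                         augment = augment_config(seed = seed)) {
  variant <- match.arg(variant)
  refine <- variant %in% c("refine_low", "refine_high")
  if (is.null(loss))
    loss <- switch(variant, base_feat = "feature_loss_l1", mcdncnn = "mse",
                   "lpips_like")
  loss <- match.arg(loss, c("mae", "mse", "feature_loss_l1", "lpips_like"))
  if (is.null(schedule)) schedule <- if (refine) "fixed" else one_cycle_schedule()
  if (is.null(regime))
    regime <- noise_regime(switch(variant, refine_low = "refine_low",
                                  refine_high = "refine_high", "standard"))
  stopifnot(batch_size >= 1, epochs >= 1, steps_per_epoch >= 1)
  structure(list(variant = variant, loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), schedule = schedule,
                 fixed_lr = fixed_lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay,
                 mixed_precision = isTRUE(mixed_precision),
                 seed = as.integer(seed), regime = regime,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 crop_size = crop_size, zero_noise_frac = zero_noise_frac,
                 augment = augment, requires_first_stage = refine),
            class = "train_config")
}

# ---- AdamW ---------------------------------------------------------------

adamw_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(as.array(p$v)))),
       v = lapply(params, function(p) array(0, dim(as.array(p$v)))),
       t = 0L)
}

adamw_step <- function(opt, params, lr, beta1, beta2, weight_decay,
                       no_decay = logical(length(params)), eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$g
    if (is.null(g)) next
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g^2
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + eps)
    if (!no_decay[i] && weight_decay > 0) upd <- upd + weight_decay * p$v
    p$v <- p$v - lr * upd
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- data plumbing -------------------------------------------------------

# Extract one 7-slice axial slab (channels k-3..k+3, edge-replicated) and
# the matching clean slice from a conformed volume pair.
training_slab <- function(noisy_data, clean_data, k, channels = 7L) {
  S <- dim(noisy_data)[3]
  half <- channels %/% 2L
  ks <- pmin(pmax(k + (-half):half, 1L), S)
  slab <- noisy_data[, , ks, drop = FALSE]
  list(noisy = slab, clean = clean_data[, , k])
}

# Cached centre-bump profiles of the variable sigma field (one per axis
# length), so training does not rebuild the full 3D field per sample.
.bump_cache <- new.env(parent = emptyenv())
bump_profile <- function(n) {
  key <- as.character(n)
  if (is.null(.bump_cache[[key]])) {
    t <- seq(0, 1, length.out = n)
    .bump_cache[[key]] <- stats::spline(c(0, 0.5, 1), c(0, 1, 0),
                                        method = "natural", xout = t)$y
  }
  .bump_cache[[key]]
}

# Rician noise realized lazily on one (possibly cropped) slab: identical in
# law to noising the full volume and then slicing, since the noise is
# i.i.d. per voxel, but an order of magnitude cheaper per training step.
noisy_slab_lazy <- function(clean_data, ri, ci, ks, sg, field_kind, seed) {
  slab <- clean_data[ri, ci, ks, drop = FALSE]
  if (sg <= 0) return(slab)
  d <- dim(clean_data)
  mult <- if (field_kind == "variable") {
    bx <- bump_profile(d[1])[ri]; by <- bump_profile(d[2])[ci]
    bz <- bump_profile(d[3])[ks]
    pmax(1 + 2 * outer(outer(bx, by), bz), 1)
  } else array(1, dim(slab))
  sgf <- sg * mult
  rng_local(seed, function() {
    n <- length(slab)
    sqrt((slab + stats::rnorm(n) * sgf)^2 + (stats::rnorm(n) * sgf)^2)
  })
}

loss_node_for <- function(denoised, clean, loss, extractor) {
  target <- array(clean, c(dim(clean)[1:2], 1L))
  if (loss == "mae") return(t_mean_abs(denoised, target))
  if (loss == "mse") return(t_mean_sq(denoised, target))
  # feature losses: run the extractor convolutions on the tape with frozen
  # weights; the target's features are constants.
  h <- t_concat_c(list(denoised, denoised, denoised))
  ht <- array(rep(clean, 3L), c(dim(clean)[1:2], 3L))
  lossn <- NULL
  for (l in seq_len(extractor$n_layers)) {
    cv <- extractor$weights[[l]]
    h <- t_relu(t_conv2d(h, cv$w, cv$b))
    ht <- nval(t_relu(t_conv2d(new_node(ht, leaf = TRUE), cv$w, cv$b)))
    if (l %in% extractor$layers) {
      term <- if (loss == "feature_loss_l1") t_mean_abs(h, ht) else t_mean_sq(h, ht)
      lossn <- if (is.null(lossn)) term else t_add_scalar_node(lossn, term)
    }
  }
  lossn
}

# Denoise the slices needed for a slab with a frozen first-stage model
# (used by the refinement variants): each channel of the second-stage slab
# is the first stage's denoised version of the corresponding slice.
first_stage_slab <- function(first_stage, noisy_data, k, R_o, channels = 7L) {
  S <- dim(noisy_data)[3]
  half <- channels %/% 2L
  ks <- pmin(pmax(k + (-half):half, 1L), S)
  out <- array(0, c(dim(noisy_data)[1:2], channels))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(ks)) {
    key <- as.character(ks[i])
    if (is.null(cache[[key]])) {
      sl <- training_slab(noisy_data, noisy_data, ks[i], channels)
      cands <- net_forward(first_stage, sl$noisy, R_o)
      Y <- combine_candidates(lapply(cands, function(cc) nval(cc)[, , 1]),
                              as.numeric(first_stage$lambdas$v))
      cache[[key]] <- sl$noisy[, , half + 1L] - Y
    }
    out[, , i] <- cache[[key]]
  }
  out
}

#' Train a denoiser on clean volumes
#'
#' Per sample: conform, draw a base sigma from the regime (a configurable
#' fraction of samples use sigma exactly 0), add Rician noise with the
#' regime's field, extract a random axial slab, augment (flip, rotation,
#' inner-scale offset), forward, loss against the clean middle slice,
#' AdamW update under the one-cycle schedule. The candidate weights lambda
#' are trained jointly but excluded from weight decay. Refinement variants
#' first pass the noisy slices through a frozen first-stage model.
#'
#' @param model an `mri_denoiser` (architecture matching the variant).
#' @param data_source list of clean `mri_volume`s (conformed or not).
#' @param config a [train_config()].
#' @param first_stage frozen first-stage model for refinement variants.
#' @param checkpoint_dir if given, a checkpoint is written per epoch.
#' @param extractor feature extractor for the perceptual losses.
#' @return list with `model`, `trace` (data.frame: step, epoch, lr, sigma,
#'   loss) and `checkpoints` (paths, possibly empty).
#' @export
train_denoiser <- function(model, data_source, config = train_config(),
                           first_stage = NULL, checkpoint_dir = NULL,
                           extractor = feature_extractor(seed = 7L)) {
  stopifnot(inherits(model, "mri_denoiser"), inherits(config, "train_config"))
  if (config$requires_first_stage && is.null(first_stage))
    stop("variant '", config$variant, "' requires a first-stage model")
  vols <- lapply(data_source, function(v)
    if (inherits(v, "conformed_volume")) v else conform(v))
  params <- model$par_list
  no_decay <- vapply(params, function(p) identical(p, model$lambdas), TRUE)
  opt <- adamw_new(params)
  fixed <- identical(config$schedule, "fixed")
  total_steps <- config$epochs * config$steps_per_epoch
  trace <- vector("list", total_steps)
  ckpts <- character(0)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    for (es in seq_len(config$steps_per_epoch)) {
      lr <- if (fixed) config$fixed_lr else
        one_cycle_lr(step, total_steps, config$schedule)
      b1 <- if (fixed) config$beta1 else
        one_cycle_beta1(step, total_steps, config$schedule)
      batch_loss <- 0
      sigma_used <- NA_real_
      for (bi in seq_len(config$batch_size)) {
        draw <- step * config$batch_size + bi
        sseed <- draw_seed(config$seed, draw)
        pick <- rng_local(sseed, function() {
          list(vol = sample.int(length(vols), 1L),
               zero = stats::runif(1) < config$zero_noise_frac,
               off = stats::runif(2))
        })
        clean <- vols[[pick$vol]]
        sg <- if (pick$zero) 0 else
          sample_training_sigma(config$regime, sseed + 1L)
        sigma_used <- sg
        d <- dim(clean$data)
        S <- d[3]
        k <- 1L + as.integer(floor(pick$off[1] * S)) %% S
        half <- model$config$input_channels %/% 2L
        ks <- pmin(pmax(k + (-half):half, 1L), S)
        cs <- config$crop_size
        if (!is.null(cs) && cs < d[1]) {
          ri <- 1L + as.integer(floor(pick$off[2] * (d[1] - cs))) + 0:(cs - 1L)
          ci <- 1L + as.integer(floor(pick$off[1] * (d[2] - cs))) + 0:(cs - 1L)
        } else {
          ri <- seq_len(d[1]); ci <- seq_len(d[2])
        }
        if (config$requires_first_stage) {
          field <- sigma_field(sg, sg, "stationary", shape = d)
          noisy <- if (sg > 0) add_rician(clean, field, seed = sseed + 2L)$data
          else clean$data
          slab <- list(noisy = first_stage_slab(first_stage, noisy, k,
                                                clean$iso_voxel,
                                                model$config$input_channels)[ri, ci, , drop = FALSE],
                       clean = clean$data[ri, ci, k])
        } else {
          slab <- list(noisy = noisy_slab_lazy(clean$data, ri, ci, ks, sg,
                                               config$regime$field_kind,
                                               sseed + 2L),
                       clean = clean$data[ri, ci, k])
        }
        aug <- augment_pair(slab$noisy, slab$clean, config$augment, draw)
        mu <- insa_factor(clean$iso_voxel / model$config$internal_res,
                          config$augment, draw)
        tg_start()
        cands <- net_forward(model, aug$noisy, clean$iso_voxel,
                             training = TRUE, insa_mu = mu,
                             mixed_precision = config$mixed_precision)
        mid <- model$config$input_channels %/% 2L + 1L
        Yc <- t_combine(cands, model$lambdas)
        den <- t_sub(new_node(aug$noisy[, , mid, drop = FALSE], leaf = TRUE), Yc)
        lossn <- loss_node_for(den, aug$clean, config$loss, extractor)
        if (!is.finite(lossn$v))
          stop(sprintf(paste0("non-finite loss at step %d (epoch %d, lr %.3g,",
                              " sigma %.4f)"), step, epoch, lr, sg))
        tg_backward(lossn)
        tg_stop()
        batch_loss <- batch_loss + lossn$v / config$batch_size
      }
      opt <- adamw_step(opt, params, lr, b1, config$beta2,
                        config$weight_decay, no_decay)
      zero_grads(params)
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, epoch = epoch, lr = lr,
                                  sigma = sigma_used, loss = batch_loss)
    }
    if (!is.null(checkpoint_dir)) {
      cp <- file.path(checkpoint_dir, sprintf("epoch_%03d.ckpt", epoch))
      save_checkpoint(model, cp, extra = list(epoch = epoch,
                                              config = config["variant"]))
      ckpts <- c(ckpts, cp)
    }
  }
  list(model = model, trace = do.call(rbind, trace), checkpoints = ckpts)
}
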