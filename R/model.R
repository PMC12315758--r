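# Network architectures: the nested maxout encoder-decoder denoiser with
# voxel-size-invariant latent rescaling and six residual noise candidates,
# plus two comparator architectures (a plain encoder-decoder with the same
# latent rescaling, and a multi-channel DnCNN).
#
# All networks are residual: they estimate the noise of the middle slice of
# a 7-slice slab, and the estimate is subtracted from that slice.

#' Architecture hyperparameters
#'
#' @param n_filt filters per convolutional block unit (CBU).
#' @param rows number of resolution rows: row 0 works at the native voxel
#'   size, row 1 at the internal resolution, rows 2..rows-1 at successively
#'   2x-pooled resolutions. The default 7-row layout yields 6 output heads.
#' @param candidates number of residual noise candidates (output heads).
#' @param internal_res internal (latent) resolution in millimetres; feature
#'   maps are bilinearly rescaled by `R_o / internal_res` after the first
#'   block, which is what makes the network voxel-size invariant.
#' @param use_batchnorm include batch normalization inside CBUs. Off by
#'   default: the batch-normalized variant is retained as an option, but the
#'   plain variant avoids the train/eval statistics gap at small batch sizes.
#' @param input_channels slab thickness fed to the network (odd; default 7).
#' @param filter_doubling double the filter count at each pooled row
#'   (UNet++-style growth) instead of keeping `n_filt` everywhere.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_filt = 64L, rows = 7L, candidates = rows - 1L,
                           internal_res = 1.0, use_batchnorm = FALSE,
                           input_channels = 7L, filter_doubling = FALSE) {
  stopifnot(n_filt >= 1, rows >= 3, internal_res > 0)
  if (input_channels %% 2L == 0L) stop("input_channels must be odd")
  if (rows == 7L && candidates != 6L)
    stop("the 7-row layout has exactly 6 candidate heads")
  if (candidates != rows - 1L)
    stop("candidates must equal rows - 1")
  structure(list(n_filt = as.integer(n_filt), rows = as.integer(rows),
                 candidates = as.integer(candidates),
                 internal_res = internal_res,
                 use_batchnorm = isTRUE(use_batchnorm),
                 input_channels = as.integer(input_channels),
                 pool_kernel = c(2L, 2L), pool_stride = 2L, pool_pad = 0L,
                 filter_doubling = isTRUE(filter_doubling)),
            class = "network_config")
}

#' A batch of 7-slice slabs
#'
#' @param data numeric array of dim `c(BS, C, H, W)`.
#' @param plane one of "axial", "coronal", "sagittal".
#' @param native_res native in-plane voxel size `R_o` in millimetres.
#' @export
slab_batch <- function(data, plane = "axial", native_res = 1.0) {
  stopifnot(length(dim(data)) == 4L, native_res > 0)
  plane <- match.arg(plane, c("axial", "coronal", "sagittal"))
  if (dim(data)[3] < 16L || dim(data)[4] < 16L)
    stop("slab spatial dimensions must be at least 16")
  structure(list(data = data, plane = plane, native_res = native_res),
            class = "slab_batch")
}

#' Elementwise maxout competition between two feature stacks
#'
#' Retains, at every spatial location and filter index, the larger of the
#' two responses, so the filter count stays constant through merges.
#' @param a,b numeric arrays of identical shape.
#' @export
maxout <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("maxout: shape mismatch")
  pmax(a, b)
}

#' Rescale feature maps between native and internal resolution
#'
#' Bilinear interpolation by the factor `F = R_o / R_i` (direction
#' `to_internal`) or its inverse (`to_native`). The result of `to_internal`
#' carries the original spatial dims as an attribute so that `to_native`
#' restores them exactly.
#'
#' @param features array `H x W x C` (or `H x W`).
#' @param R_o,R_i native and internal resolutions in mm.
#' @param direction "to_internal" or "to_native".
#' @export
vinn_rescale <- function(features, R_o, R_i,
                         direction = c("to_internal", "to_native")) {
  direction <- match.arg(direction)
  stopifnot(R_o > 0, R_i > 0)
  x <- as_cube(features)
  h <- dim(x)[1]; w <- dim(x)[2]
  f <- if (direction == "to_internal") R_o / R_i else R_i / R_o
  nd <- attr(features, "native_dim")
  if (direction == "to_native" && !is.null(nd)) {
    oh <- nd[1]; ow <- nd[2]
  } else {
    oh <- as.integer(round(h * f)); ow <- as.integer(round(w * f))
  }
  if (oh < 4L || ow < 4L) stop("vinn_rescale: resulting feature map too small")
  y <- cpp_resize_bilinear(x, oh, ow)
  if (length(dim(features)) == 2L) dim(y) <- dim(y)[1:2]
  if (direction == "to_internal") attr(y, "native_dim") <- c(h, w)
  y
}

# ---- CBU blocks -----------------------------------------------------------

rng_local <- function(seed, fun) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  fun()
}

conv_init <- function(c_in, c_out, k, scale = 1) {
  fan_in <- c_in * k * k
  w <- matrix(stats::rnorm(c_out * fan_in, sd = scale * sqrt(2 / fan_in)),
              nrow = c_out)
  list(w = tg_param(w), b = tg_param(rep(0, c_out)))
}

bn_new <- function(c_out) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, c_out); st$var <- rep(1, c_out)
  list(gamma = tg_param(rep(1, c_out)), beta = tg_param(rep(0, c_out)), state = st)
}

#' Create a convolutional block unit (CBU)
#'
#' Standard blocks run three 3x3 convolutions (padding 1) with PReLU
#' non-linearities, one internal maxout, and optional batch normalization.
#' The input block uses two convolutions whose outputs compete through a
#' maxout. Output blocks append a 1x1 convolution collapsing the features
#' to a single channel (the residual noise candidate).
#'
#' @param config a [network_config()].
#' @param kind "input", "standard" or "output".
#' @param c_in,c_out channel counts (default `n_filt`).
#' @export
cbu_init <- function(config, kind = c("standard", "input", "output"),
                     c_in = NULL, c_out = config$n_filt) {
  kind <- match.arg(kind)
  if (is.null(c_in))
    c_in <- if (kind == "input") config$input_channels else config$n_filt
  bn <- config$use_batchnorm
  bl <- list(kind = kind, c_in = c_in, c_out = c_out, use_batchnorm = bn)
  if (kind == "input") {
    bl$conv1 <- conv_init(c_in, c_out, 3L)
    bl$conv2 <- conv_init(c_out, c_out, 3L)
    bl$a1 <- tg_param(rep(0.25, c_out)); bl$a2 <- tg_param(rep(0.25, c_out))
    if (bn) { bl$bn1 <- bn_new(c_out); bl$bn2 <- bn_new(c_out) }
  } else {
    bl$conv1 <- conv_init(c_in, c_out, 3L)
    bl$conv2 <- conv_init(c_out, c_out, 3L)
    bl$conv3 <- conv_init(c_out, c_out, 3L)
    bl$a1 <- tg_param(rep(0.25, c_out)); bl$a2 <- tg_param(rep(0.25, c_out))
    bl$a3 <- tg_param(rep(0.25, c_out))
    if (bn) { bl$bn1 <- bn_new(c_out); bl$bn2 <- bn_new(c_out); bl$bn3 <- bn_new(c_out) }
    if (kind == "output") bl$head <- conv_init(c_out, 1L, 1L, scale = 0.3)
  }
  class(bl) <- "cbu_block"
  bl
}

cbu_fwd_node <- function(bl, x, training = FALSE) {
  bn <- bl$use_batchnorm
  if (bl$kind == "input") {
    c1 <- t_conv2d(x, bl$conv1$w, bl$conv1$b)
    if (bn) c1 <- t_batchnorm(c1, bl$bn1$gamma, bl$bn1$beta, bl$bn1$state, training)
    h1 <- t_prelu(c1, bl$a1)
    c2 <- t_conv2d(h1, bl$conv2$w, bl$conv2$b)
    if (bn) c2 <- t_batchnorm(c2, bl$bn2$gamma, bl$bn2$beta, bl$bn2$state, training)
    return(t_prelu(t_maxout2(c1, c2), bl$a2))
  }
  c1 <- t_conv2d(x, bl$conv1$w, bl$conv1$b)
  if (bn) c1 <- t_batchnorm(c1, bl$bn1$gamma, bl$bn1$beta, bl$bn1$state, training)
  h1 <- t_prelu(c1, bl$a1)
  c2 <- t_conv2d(h1, bl$conv2$w, bl$conv2$b)
  if (bn) c2 <- t_batchnorm(c2, bl$bn2$gamma, bl$bn2$beta, bl$bn2$state, training)
  h2 <- t_prelu(t_maxout2(h1, c2), bl$a2)
  c3 <- t_conv2d(h2, bl$conv3$w, bl$conv3$b)
  if (bn) c3 <- t_batchnorm(c3, bl$bn3$gamma, bl$bn3$beta, bl$bn3$state, training)
  t_prelu(c3, bl$a3)
}

cbu_head_node <- function(bl, feats) t_conv2d(feats, bl$head$w, bl$head$b, k = 1L, pad = 0L)

#' Run one CBU forward on a plain array
#'
#' @param x array `H x W x C_in`.
#' @param block a block from [cbu_init()].
#' @param training use batch statistics (if batch-normalized).
#' @return array `H x W x C_out`; for output blocks, `H x W x 1` (the
#'   collapsed residual candidate).
#' @export
cbu_forward <- function(x, block, training = FALSE) {
  x <- as_cube(x)
  if (dim(x)[3] != block$c_in)
    stop(sprintf("cbu_forward: expected %d input channels, got %d",
                 block$c_in, dim(x)[3]))
  f <- cbu_fwd_node(block, new_node(x, leaf = TRUE), training = training)
  if (block$kind == "output") nval(cbu_head_node(block, f)) else nval(f)
}

block_params <- function(bl) {
  out <- list()
  for (nm in c("conv1", "conv2", "conv3", "head"))
    if (!is.null(bl[[nm]])) out <- c(out, list(bl[[nm]]$w, bl[[nm]]$b))
  for (nm in c("a1", "a2", "a3"))
    if (!is.null(bl[[nm]])) out <- c(out, list(bl[[nm]]))
  for (nm in c("bn1", "bn2", "bn3"))
    if (!is.null(bl[[nm]])) out <- c(out, list(bl[[nm]]$gamma, bl[[nm]]$beta))
  out
}

#' Number of trainable parameters
#' @param x a network or a CBU block.
#' @export
count_params <- function(x) {
  ps <- if (inherits(x, "cbu_block")) block_params(x) else x$par_list
  sum(vapply(ps, function(p) length(p$v), 0))
}

# Filters at row i (0-based): constant, or doubling below row 1.
row_filters <- function(config, i) {
  if (!config$filter_doubling) return(config$n_filt)
  as.integer(config$n_filt * 2^max(0L, i - 1L))
}

# ---- nested architecture --------------------------------------------------

#' Build the nested maxout denoiser
#'
#' The 7-row layout: row 0 at native resolution, row 1 at the internal
#' resolution (reached by bilinear latent rescaling), rows 2..6 by 2x2 max
#' pooling with index passing. Nested blocks at (i, j) merge, through
#' maxout, the max-unpooled block (i+1, j-1) with all same-row predecessors
#' (i, 0..j-1); row-0 columns merge the up-rescaled (1, j-1) block with all
#' row-0 predecessors and end in an output head producing the residual
#' noise candidate Y_j. The candidates are combined by trainable scalar
#' weights lambda (initialized to 1).
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `mri_denoiser`.
#' @export
build_nested_denoiser <- function(config = network_config(), seed = 0L) {
  rng_local(seed, function() {
    R <- config$rows
    blocks <- list()
    blocks[["b0_0"]] <- cbu_init(config, "input", c_out = row_filters(config, 0L))
    blocks[["b1_0"]] <- cbu_init(config, "standard",
                                 c_in = row_filters(config, 0L),
                                 c_out = row_filters(config, 1L))
    for (i in 2:(R - 1L))
      blocks[[sprintf("b%d_0", i)]] <-
        cbu_init(config, "standard", c_in = row_filters(config, i - 1L),
                 c_out = row_filters(config, i))
    proj <- list()
    for (j in seq_len(config$candidates)) {
      for (i in rev(seq_len(R - 1L - j))) {  # i = (R-1-j) .. 1
        nf <- row_filters(config, i)
        nf_below <- row_filters(config, i + 1L)
        if (nf_below != nf)
          proj[[sprintf("p%d_%d", i, j)]] <- conv_init(nf_below, nf, 1L)
        blocks[[sprintf("b%d_%d", i, j)]] <-
          cbu_init(config, "standard", c_in = nf, c_out = nf)
      }
      blocks[[sprintf("b0_%d", j)]] <-
        cbu_init(config, "output", c_in = row_filters(config, 0L),
                 c_out = row_filters(config, 0L))
    }
    lambdas <- tg_param(rep(1, config$candidates))
    net <- structure(list(arch = "nested", config = config, blocks = blocks,
                          proj = proj, lambdas = lambdas,
                          version = "mridenoise-ckpt-1"),
                     class = "mri_denoiser")
    net$par_list <- c(unlist(lapply(blocks, block_params), use.names = FALSE),
                      unlist(lapply(proj, function(p) list(p$w, p$b)),
                             use.names = FALSE),
                      list(lambdas))
    net
  })
}

pad_multiple <- function(n, m) as.integer(ceiling(n / m) * m)

# Forward pass for one slab [H, W, C]; returns list of candidate nodes.
fwd_nested <- function(net, x, R_o, training = FALSE, insa_mu = 0,
                       mixed_precision = FALSE) {
  cfg <- net$config
  R <- cfg$rows
  H0 <- dim(x)[1]; W0 <- dim(x)[2]
  xn <- if (is_node(x)) x else new_node(x, leaf = TRUE)
  mp <- function(nd) if (mixed_precision) t_round_single(nd) else nd
  f <- list()
  f[["0_0"]] <- mp(cbu_fwd_node(net$blocks[["b0_0"]], xn, training))
  Fi <- R_o / cfg$internal_res + insa_mu
  if (Fi <= 0) stop("non-positive latent rescale factor")
  Hi <- max(4L, as.integer(round(H0 * Fi)))
  Wi <- max(4L, as.integer(round(W0 * Fi)))
  m <- as.integer(2^(R - 2L))
  Hp <- pad_multiple(Hi, m); Wp <- pad_multiple(Wi, m)
  g <- t_pad_to(t_resize_bilinear(f[["0_0"]], Hi, Wi), Hp, Wp)
  f[["1_0"]] <- mp(cbu_fwd_node(net$blocks[["b1_0"]], g, training))
  pools <- list()
  for (i in 2:(R - 1L)) {
    pl <- t_maxpool2(f[[sprintf("%d_0", i - 1L)]])
    pools[[i]] <- pl
    f[[sprintf("%d_0", i)]] <-
      mp(cbu_fwd_node(net$blocks[[sprintf("b%d_0", i)]], pl, training))
  }
  cands <- vector("list", cfg$candidates)
  for (j in seq_len(cfg$candidates)) {
    for (i in rev(seq_len(R - 1L - j))) {
      below <- f[[sprintf("%d_%d", i + 1L, j - 1L)]]
      pl <- pools[[i + 1L]]
      up <- t_maxunpool2(below, pl$idx, pl$in_hw[1], pl$in_hw[2])
      pj <- net$proj[[sprintf("p%d_%d", i, j)]]
      if (!is.null(pj)) up <- t_conv2d(up, pj$w, pj$b, k = 1L, pad = 0L)
      ins <- c(list(up), lapply(0:(j - 1L), function(q) f[[sprintf("%d_%d", i, q)]]))
      f[[sprintf("%d_%d", i, j)]] <-
        mp(cbu_fwd_node(net$blocks[[sprintf("b%d_%d", i, j)]],
                        t_maxout_all(ins), training))
    }
    below <- t_crop_to(f[[sprintf("1_%d", j - 1L)]], Hi, Wi)
    up <- t_resize_bilinear(below, H0, W0)
    ins <- c(list(up), lapply(0:(j - 1L), function(q) f[[sprintf("0_%d", q)]]))
    bl <- net$blocks[[sprintf("b0_%d", j)]]
    f[[sprintf("0_%d", j)]] <- mp(cbu_fwd_node(bl, t_maxout_all(ins), training))
    cands[[j]] <- cbu_head_node(bl, f[[sprintf("0_%d", j)]])
  }
  cands
}

# ---- comparator architectures --------------------------------------------

#' Build the multi-channel DnCNN comparator
#'
#' Seventeen stacked 3x3 convolutions with 64 filters, batch normalization
#' and ReLU on the hidden layers, residual single-channel output.
#' @param config a [network_config()]; `n_filt` and `input_channels` are
#'   honored (64 and 7 by convention).
#' @param seed weight-initialization seed.
#' @export
build_mcdncnn <- function(config = network_config(n_filt = 64L), seed = 0L) {
  rng_local(seed, function() {
    nf <- config$n_filt
    layers <- vector("list", 17L)
    layers[[1]] <- list(conv = conv_init(config$input_channels, nf, 3L))
    for (l in 2:16)
      layers[[l]] <- list(conv = conv_init(nf, nf, 3L), bn = bn_new(nf))
    layers[[17]] <- list(conv = conv_init(nf, 1L, 3L, scale = 0.3))
    net <- structure(list(arch = "mcdncnn", config = config, layers = layers,
                          lambdas = tg_param(1),
                          version = "mridenoise-ckpt-1"),
                     class = "mri_denoiser")
    ps <- list()
    for (l in layers) {
      ps <- c(ps, list(l$conv$w, l$conv$b))
      if (!is.null(l$bn)) ps <- c(ps, list(l$bn$gamma, l$bn$beta))
    }
    net$par_list <- ps
    net
  })
}

fwd_mcdncnn <- function(net, x, R_o, training = FALSE, insa_mu = 0,
                        mixed_precision = FALSE) {
  xn <- if (is_node(x)) x else new_node(x, leaf = TRUE)
  h <- t_relu(t_conv2d(xn, net$layers[[1]]$conv$w, net$layers[[1]]$conv$b))
  for (l in 2:16) {
    ly <- net$layers[[l]]
    h <- t_conv2d(h, ly$conv$w, ly$conv$b)
    h <- t_batchnorm(h, ly$bn$gamma, ly$bn$beta, ly$bn$state, training)
    h <- t_relu(h)
  }
  list(t_conv2d(h, net$layers[[17]]$conv$w, net$layers[[17]]$conv$b))
}

#' Build the plain encoder-decoder comparator with latent rescaling
#'
#' A five-level (including the bottleneck) encoder-decoder: a 32-filter
#' input CBU at native resolution, latent rescaling to the internal
#' resolution, filter doubling per level up to a 512-filter bottleneck,
#' max pooling with indices passed to the matching unpooling, concatenating
#' skip connections, and a residual single-channel output head.
#' @param config a [network_config()]; `n_filt` is the first-level filter
#'   count (32 by convention) and the bottleneck has `n_filt * 16`.
#' @param seed weight-initialization seed.
#' @export
build_unet_vinn <- function(config = network_config(n_filt = 32L), seed = 0L) {
  rng_local(seed, function() {
    nf <- config$n_filt
    nlev <- 5L
    filt <- nf * 2^(0:(nlev - 1L))  # 32 64 128 256 512
    enc <- list(); dec <- list()
    inp <- cbu_init(config, "input", c_out = nf)
    enc[[1]] <- cbu_init(config, "standard", c_in = nf, c_out = filt[1])
    for (l in 2:nlev)
      enc[[l]] <- cbu_init(config, "standard", c_in = filt[l - 1L], c_out = filt[l])
    for (l in (nlev - 1L):1)
      dec[[l]] <- cbu_init(config, "standard", c_in = filt[l + 1L] + filt[l],
                           c_out = filt[l])
    outb <- cbu_init(config, "output", c_in = nf, c_out = nf)
    net <- structure(list(arch = "unet_vinn", config = config, input = inp,
                          enc = enc, dec = dec, outb = outb,
                          lambdas = tg_param(1), n_levels = nlev,
                          version = "mridenoise-ckpt-1"),
                     class = "mri_denoiser")
    net$par_list <- c(block_params(inp),
                      unlist(lapply(enc, block_params), use.names = FALSE),
                      unlist(lapply(dec, block_params), use.names = FALSE),
                      block_params(outb))
    net
  })
}

fwd_unet_vinn <- function(net, x, R_o, training = FALSE, insa_mu = 0,
                          mixed_precision = FALSE) {
  cfg <- net$config
  H0 <- dim(nval(x))[1]; W0 <- dim(nval(x))[2]
  xn <- if (is_node(x)) x else new_node(x, leaf = TRUE)
  f0 <- cbu_fwd_node(net$input, xn, training)
  Fi <- R_o / cfg$internal_res + insa_mu
  if (Fi <= 0) stop("non-positive latent rescale factor")
  Hi <- max(4L, as.integer(round(H0 * Fi)))
  Wi <- max(4L, as.integer(round(W0 * Fi)))
  m <- as.integer(2^(net$n_levels - 1L))
  Hp <- pad_multiple(Hi, m); Wp <- pad_multiple(Wi, m)
  g <- t_pad_to(t_resize_bilinear(f0, Hi, Wi), Hp, Wp)
  skips <- list(); pools <- list()
  h <- cbu_fwd_node(net$enc[[1]], g, training)
  skips[[1]] <- h
  for (l in 2:net$n_levels) {
    pl <- t_maxpool2(h)
    pools[[l]] <- pl
    h <- cbu_fwd_node(net$enc[[l]], pl, training)
    if (l < net$n_levels) skips[[l]] <- h
  }
  for (l in (net$n_levels - 1L):1) {
    pl <- pools[[l + 1L]]
    up <- t_maxunpool2(h, pl$idx, pl$in_hw[1], pl$in_hw[2])
    h <- cbu_fwd_node(net$dec[[l]], t_concat_c(list(up, skips[[l]])), training)
  }
  up <- t_resize_bilinear(t_crop_to(h, Hi, Wi), H0, W0)
  feats <- cbu_fwd_node(net$outb, t_maxout2(up, f0), training)
  list(cbu_head_node(net$outb, feats))
}

net_forward <- function(net, x, R_o, training = FALSE, insa_mu = 0,
                        mixed_precision = FALSE) {
  switch(net$arch,
         nested = fwd_nested(net, x, R_o, training, insa_mu, mixed_precision),
         mcdncnn = fwd_mcdncnn(net, x, R_o, training, insa_mu, mixed_precision),
         unet_vinn = fwd_unet_vinn(net, x, R_o, training, insa_mu, mixed_precision),
         stop("unknown architecture: ", net$arch))
}

# ---- candidate combination and slab denoising -----------------------------

#' Combine residual noise candidates by their lambda weights
#'
#' `Y = sum(lambda_N * Y_N) / sum(lambda_N)`.
#'
#' @param cands list with elements `Y` (list of equally shaped residual
#'   maps) and `lambdas` (numeric weights), or such a pair given separately.
#' @param lambdas numeric weights if `cands` is a bare list of maps.
#' @export
combine_candidates <- function(cands, lambdas = NULL) {
  if (is.list(cands) && !is.null(cands$Y)) {
    lambdas <- cands$lambdas
    cands <- cands$Y
  }
  stopifnot(length(cands) == length(lambdas))
  dims <- lapply(cands, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("combine_candidates: candidate shapes differ")
  L <- sum(lambdas)
  if (abs(L) < 1e-12) stop("degenerate candidate combination: sum(lambda) is zero")
  Reduce(`+`, Map(function(y, l) y * l, cands, as.list(lambdas))) / L
}

#' Denoise the middle slices of a slab batch
#'
#' Runs the network forward, combines the candidates with the trained
#' lambda weights, and subtracts the combined residual from each slab's
#' middle channel.
#'
#' @param network an `mri_denoiser`.
#' @param slab a [slab_batch()].
#' @return array `BS x H x W` of denoised middle slices.
#' @export
denoise_slab <- function(network, slab) {
  stopifnot(inherits(slab, "slab_batch"))
  d <- dim(slab$data)
  if (d[2] != network$config$input_channels)
    stop(sprintf("slab has %d channels; network expects %d",
                 d[2], network$config$input_channels))
  out <- array(0, c(d[1], d[3], d[4]))
  mid <- (d[2] + 1L) %/% 2L
  for (b in seq_len(d[1])) {
    x <- aperm(slab$data[b, , , , drop = FALSE][1, , , ], c(2, 3, 1))
    cands <- net_forward(network, x, slab$native_res, training = FALSE)
    Y <- combine_candidates(lapply(cands, function(cc) nval(cc)[, , 1]),
                            as.numeric(network$lambdas$v))
    out[b, , ] <- x[, , mid] - Y
  }
  out
}

# ---- checkpointing --------------------------------------------------------

net_state <- function(net) lapply(net$par_list, function(p) p$v)

net_load_state <- function(net, state) {
  stopifnot(length(state) == length(net$par_list))
  for (i in seq_along(state)) {
    stopifnot(length(net$par_list[[i]]$v) == length(state[[i]]))
    net$par_list[[i]]$v <- state[[i]]
  }
  invisible(net)
}

bn_states <- function(net) {
  out <- list()
  grab <- function(bl, key) {
    for (nm in c("bn1", "bn2", "bn3"))
      if (!is.null(bl[[nm]]))
        out[[paste(key, nm, sep = ".")]] <<- list(mean = bl[[nm]]$state$mean,
                                                  var = bl[[nm]]$state$var)
  }
  if (net$arch == "nested") {
    for (k in names(net$blocks)) grab(net$blocks[[k]], k)
  } else if (net$arch == "mcdncnn") {
    for (l in seq_along(net$layers))
      if (!is.null(net$layers[[l]]$bn))
        out[[sprintf("l%d", l)]] <- list(mean = net$layers[[l]]$bn$state$mean,
                                         var = net$layers[[l]]$bn$state$var)
  } else {
    grab(net$input, "input")
    for (l in seq_along(net$enc)) grab(net$enc[[l]], sprintf("enc%d", l))
    for (l in seq_along(net$dec))
      if (!is.null(net$dec[[l]])) grab(net$dec[[l]], sprintf("dec%d", l))
    grab(net$outb, "outb")
  }
  out
}

bn_load_states <- function(net, states) {
  put <- function(bl, key) {
    for (nm in c("bn1", "bn2", "bn3")) {
      k <- paste(key, nm, sep = ".")
      if (!is.null(bl[[nm]]) && !is.null(states[[k]])) {
        bl[[nm]]$state$mean <- states[[k]]$mean
        bl[[nm]]$state$var <- states[[k]]$var
      }
    }
  }
  if (net$arch == "nested") {
    for (k in names(net$blocks)) put(net$blocks[[k]], k)
  } else if (net$arch == "mcdncnn") {
    for (l in seq_along(net$layers))
      if (!is.null(net$layers[[l]]$bn) && !is.null(states[[sprintf("l%d", l)]])) {
        net$layers[[l]]$bn$state$mean <- states[[sprintf("l%d", l)]]$mean
        net$layers[[l]]$bn$state$var <- states[[sprintf("l%d", l)]]$var
      }
  } else {
    put(net$input, "input")
    for (l in seq_along(net$enc)) put(net$enc[[l]], sprintf("enc%d", l))
    for (l in seq_along(net$dec))
      if (!is.null(net$dec[[l]])) put(net$dec[[l]], sprintf("dec%d", l))
    put(net$outb, "outb")
  }
  invisible(net)
}

#' Save / load a network checkpoint
#'
#' A checkpoint stores the architecture name, configuration, all parameter
#' values (including the candidate weights lambda), batch-normalization
#' running moments, and an optional training state, under a version stamp.
#' @param network an `mri_denoiser`.
#' @param path file path.
#' @param extra optional list stored verbatim (e.g. training progress).
#' @export
save_checkpoint <- function(network, path, extra = NULL) {
  obj <- list(version = network$version, arch = network$arch,
              config = network$config, state = net_state(network),
              bn = bn_states(network), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "mridenoise-ckpt-1"))
    stop("unrecognized checkpoint version: ", obj$version)
  net <- switch(obj$arch,
                nested = build_nested_denoiser(obj$config),
                mcdncnn = build_mcdncnn(obj$config),
                unet_vinn = build_unet_vinn(obj$config))
  net_load_state(net, obj$state)
  bn_load_states(net, obj$bn)
  net$extra <- obj$extra
  net
}

#' Set every output head (and lambda-independent residual path) to zero
#'
#' Produces an identity denoiser: with all residual candidates zero, the
#' denoised slice equals the input middle slice exactly. Useful as a debug
#' checkpoint and for pipeline-identity tests.
#' @param network an `mri_denoiser`.
#' @export
zero_residual <- function(network) {
  if (network$arch == "nested") {
    for (j in seq_len(network$config$candidates)) {
      bl <- network$blocks[[sprintf("b0_%d", j)]]
      bl$head$w$v[] <- 0; bl$head$b$v[] <- 0
    }
  } else if (network$arch == "mcdncnn") {
    network$layers[[17]]$conv$w$v[] <- 0
    network$layers[[17]]$conv$b$v[] <- 0
  } else {
    network$outb$head$w$v[] <- 0
    network$outb$head$b$v[] <- 0
  }
  invisible(network)
}
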