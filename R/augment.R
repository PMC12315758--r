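# Training-time augmentation: horizontal flips, small in-plane rotations,
# and inner-scale augmentation (inSA) of the latent rescale factor.

#' Augmentation configuration
#'
#' @param flip_prob probability of a horizontal flip (default 0.5).
#' @param rot_max_deg rotation angles are uniform on
#'   `[-rot_max_deg, rot_max_deg]` degrees (default 5).
#' @param insa_std standard deviation of the zero-mean inner-scale offset
#'   added to the latent rescale factor (default 0.1).
#' @param seed base seed; each draw index derives its own stream from it.
#' @export
augment_config <- function(flip_prob = 0.5, rot_max_deg = 5, insa_std = 0.1,
                           seed = 0L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, rot_max_deg >= 0, insa_std >= 0)
  structure(list(flip_prob = flip_prob, rot_max_deg = rot_max_deg,
                 insa_std = insa_std, seed = as.integer(seed)),
            class = "augment_config")
}

draw_seed <- function(seed, draw_index) {
  as.integer((as.double(seed) * 1000003 + as.double(draw_index) * 7919 + 12345) %%
               2147483647)
}

#' Sample inner-scale augmentation offsets
#'
#' Zero-mean Gaussian draws with standard deviation `insa_std`, added to
#' the latent rescale factor `F = R_o / R_i` during training. Deterministic
#' given `(seed, draw_index)`.
#' @param config an [augment_config()].
#' @param draw_index integer draw index (vectorized).
#' @export
sample_insa_offset <- function(config, draw_index) {
  stopifnot(inherits(config, "augment_config"))
  if (config$insa_std == 0) return(rep(0, length(draw_index)))
  vapply(draw_index, function(i) {
    rng_local(draw_seed(config$seed, i),
              function() stats::rnorm(1, 0, config$insa_std))
  }, 0)
}

# inSA offset guarded against non-positive rescale factors: redraw from
# successive sub-streams until F + mu > 0.
insa_factor <- function(F, config, draw_index) {
  mu <- sample_insa_offset(config, draw_index)
  tries <- 0L
  while (F + mu <= 0 && tries < 100L) {
    tries <- tries + 1L
    mu <- rng_local(draw_seed(config$seed, draw_index) + tries,
                    function() stats::rnorm(1, 0, config$insa_std))
  }
  if (F + mu <= 0) mu <- 0
  mu
}

#' Sample a geometric augmentation transform
#'
#' @param config an [augment_config()].
#' @param draw_index integer draw index.
#' @return list with `flip` (logical) and `angle_deg` (uniform on
#'   `[-rot_max_deg, rot_max_deg]`).
#' @export
sample_augment <- function(config, draw_index) {
  stopifnot(inherits(config, "augment_config"))
  rng_local(draw_seed(config$seed, draw_index) + 1L, function() {
    list(flip = stats::runif(1) < config$flip_prob,
         angle_deg = stats::runif(1, -config$rot_max_deg, config$rot_max_deg))
  })
}

apply_transform_slice <- function(sl, tr) {
  if (tr$flip) sl <- sl[, rev(seq_len(ncol(sl)))]
  if (tr$angle_deg != 0) sl <- cpp_rotate_bilinear(sl, tr$angle_deg)
  sl
}

#' Apply the same geometric augmentation to a slab and its clean target
#'
#' The identical flip decision and rotation angle are applied to every
#' channel of the noisy slab and to the clean slice, keeping input and
#' target geometrically consistent. Rotation uses bilinear interpolation
#' with zero fill (the background is air after conforming).
#'
#' @param noisy array `H x W x C` (slice stack).
#' @param clean matrix `H x W` (clean middle slice).
#' @param config an [augment_config()].
#' @param draw_index integer draw index.
#' @param transform optional forced transform (as from [sample_augment()]).
#' @return list(noisy, clean, transform).
#' @export
augment_pair <- function(noisy, clean, config, draw_index = 1L,
                         transform = NULL) {
  noisy <- as_cube(noisy)
  stopifnot(identical(dim(noisy)[1:2], dim(clean)[1:2]))
  tr <- if (is.null(transform)) sample_augment(config, draw_index) else transform
  out <- noisy
  for (c in seq_len(dim(noisy)[3]))
    out[, , c] <- apply_transform_slice(noisy[, , c], tr)
  list(noisy = out, clean = apply_transform_slice(clean, tr), transform = tr)
}
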