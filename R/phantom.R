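# Synthetic multi-tissue head phantoms: nested ellipsoids with per-tissue
# mean intensities, a thin bright shell mimicking cortex (so that
# over-smoothing is detectable), smooth low-frequency texture, and an
# optional multiplicative bias field.  Deterministic given the seed.

#' Phantom specification
#'
#' Tissues are nested ellipsoids given as semi-axis fractions of the half
#' field of view (in mm) plus a mean intensity in [0, 1]; later entries
#' overwrite earlier ones, so they are listed outermost first. The default
#' set is head/CSF 0.30, a thin bright shell 0.95 (cortex-like
#' high-frequency structure), gray matter 0.75, white matter 0.55, and a
#' ventricle 0.15, over a zero (air) background.
#'
#' @param shape grid dims.
#' @param voxel_size mm triple.
#' @param tissues list of `list(semiaxes = <fractions>, intensity = <mean>)`.
#' @param texture_amp amplitude of the smooth within-tissue texture.
#' @param bias_amp amplitude of the smooth multiplicative bias field.
#' @param seed integer seed.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size = c(1, 1, 1),
                         tissues = NULL, texture_amp = 0.02, bias_amp = 0.05,
                         seed = 0L) {
  if (is.null(tissues))
    tissues <- list(
      list(semiaxes = c(0.92, 0.88, 0.85), intensity = 0.30),
      list(semiaxes = c(0.80, 0.77, 0.74), intensity = 0.95),
      list(semiaxes = c(0.74, 0.71, 0.68), intensity = 0.75),
      list(semiaxes = c(0.58, 0.55, 0.52), intensity = 0.55),
      list(semiaxes = c(0.16, 0.20, 0.14), intensity = 0.15))
  for (t in tissues) {
    stopifnot(length(t$semiaxes) == 3L, t$intensity >= 0, t$intensity <= 1)
    if (any(t$semiaxes > 1))
      stop("ellipsoid exceeds the grid (semi-axis fraction > 1)")
  }
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 tissues = tissues, texture_amp = texture_amp,
                 bias_amp = bias_amp, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, voxel_size, semiaxes_frac) {
  half_fov <- (shape - 1) / 2 * voxel_size
  ax <- semiaxes_frac * half_fov
  co <- lapply(1:3, function(k) ((seq_len(shape[k]) - 1) - (shape[k] - 1) / 2) *
                 voxel_size[k] / ax[k])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  array(d2 <= 1, shape)
}

smooth_field <- function(shape, coarse_div, seed) {
  cs <- pmax(2L, shape %/% coarse_div)
  g <- rng_local(seed, function() array(stats::rnorm(prod(cs)), cs))
  cpp_resize_trilinear(g, shape[1], shape[2], shape[3])
}

#' Generate a phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return an `mri_volume` on the unit scale (RAS orientation).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dat <- array(0, spec$shape)
  for (t in spec$tissues)
    dat[ellipsoid_mask(spec$shape, spec$voxel_size, t$semiaxes)] <- t$intensity
  inside <- dat > 0
  if (spec$texture_amp > 0) {
    tex <- smooth_field(spec$shape, 4L, spec$seed + 1L)
    dat[inside] <- dat[inside] + spec$texture_amp * tex[inside]
  }
  if (spec$bias_amp > 0) {
    bf <- smooth_field(spec$shape, 8L, spec$seed + 2L)
    dat[inside] <- dat[inside] * (1 + spec$bias_amp * tanh(bf[inside]))
  }
  dat <- pmin(pmax(dat, 0), 1)
  volume(dat, spec$voxel_size, "RAS", "unit_0_1")
}

#' Generate a (noisy, clean) training pair
#'
#' The clean member is the conformed phantom; the noisy member adds Rician
#' noise with a base sigma drawn from the regime and the regime's field
#' kind (spatially variable or stationary).
#'
#' @param spec a [phantom_spec()].
#' @param regime a [noise_regime()].
#' @param seed integer seed (sigma draw and noise realization).
#' @param base_sigma optional fixed base sigma overriding the regime draw.
#' @return list(noisy, clean, base_sigma, field).
#' @export
make_pair <- function(spec, regime = noise_regime("standard"), seed = 0L,
                      base_sigma = NULL) {
  clean <- conform(make_phantom(spec))
  sg <- if (is.null(base_sigma)) sample_training_sigma(regime, seed) else base_sigma
  field <- if (regime$field_kind == "variable" && sg > 0)
    variable_sigma_field(dim(clean$data), sg)
  else sigma_field(sg, sg, "stationary", shape = dim(clean$data))
  noisy <- if (sg > 0) add_rician(clean, field, seed = seed + 1L) else clean
  list(noisy = noisy, clean = clean, base_sigma = sg, field = field)
}

#' Registry of standard phantom fixtures
#'
#' * `fast32`: a 32 cube, 1 mm isotropic, for fast tests.
#' * `train64`: ten 64 cubes with jittered geometry and seeds, the toy
#'   training set.
#' * `aniso96`: a 96 cube with anisotropic 1.0 x 1.0 x 1.2 mm voxels, for
#'   conforming tests.
#'
#' @param name fixture name.
#' @return a `phantom_spec`, or a list of them for `train64`.
#' @export
phantom_fixture <- function(name = c("fast32", "train64", "aniso96")) {
  name <- match.arg(name)
  switch(name,
         fast32 = phantom_spec(shape = c(32L, 32L, 32L), seed = 101L),
         aniso96 = phantom_spec(shape = c(96L, 96L, 96L),
                                voxel_size = c(1, 1, 1.2), seed = 301L),
         train64 = lapply(1:10, function(i) {
           jit <- 1 - 0.05 * ((i - 1) %% 3)
           tis <- phantom_spec()$tissues
           for (k in seq_along(tis)) tis[[k]]$semiaxes <- tis[[k]]$semiaxes * jit
           phantom_spec(shape = c(64L, 64L, 64L), tissues = tis,
                        seed = 200L + i)
         }))
}
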