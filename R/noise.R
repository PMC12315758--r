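# Rician noise model and the training noise regimes: magnitude MRI noise
# arises from zero-mean Gaussian noise in the two quadrature channels, so a
# noise-free intensity A becomes sqrt((A + n1)^2 + n2^2).  Training uses
# either a stationary sigma or a spatially variable field that triples
# towards the volume centre.

#' Rice probability density
#'
#' `p(M) = (M / sigma^2) exp(-(M^2 + A^2) / (2 sigma^2)) I0(A M / sigma^2)`,
#' evaluated stably through the exponentially scaled Bessel function. With
#' `A = 0` this is the Rayleigh density (signal-free background); for
#' `A / sigma > 3` it approaches a Gaussian centred near `sqrt(A^2 + sigma^2)`.
#'
#' @param M magnitude value(s), `>= 0`.
#' @param A noise-free intensity, `>= 0`.
#' @param sigma per-channel Gaussian standard deviation, `> 0`.
#' @export
rice_pdf <- function(M, A, sigma) {
  stopifnot(all(M >= 0), A >= 0, sigma >= 0)
  if (sigma == 0) stop("rice_pdf: sigma must be positive (degenerate density)")
  z <- A * M / sigma^2
  (M / sigma^2) * exp(-(M - A)^2 / (2 * sigma^2)) *
    besselI(z, 0, expon.scaled = TRUE)
}

#' Rice cumulative distribution (numerical)
#'
#' Trapezoid integration of [rice_pdf()] on a dense grid; accurate to about
#' 1e-7, sufficient for distributional goodness-of-fit tests.
#' @inheritParams rice_pdf
#' @param q quantile(s).
#' @export
rice_cdf <- function(q, A, sigma) {
  hi <- A + 12 * sigma
  g <- seq(0, hi, length.out = 8192L)
  p <- rice_pdf(g, A, sigma)
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(g)))
  cdf <- pmin(cdf / max(cdf[length(cdf)], 1), 1)
  stats::approx(g, cdf, xout = pmin(pmax(q, 0), hi), rule = 2)$y
}

#' Per-voxel noise standard-deviation field
#'
#' @param data 3D array of sigma values (fractions of the unit intensity
#'   range), or a scalar recycled over `shape`.
#' @param base_sigma the scalar base sigma.
#' @param kind "stationary" or "variable".
#' @param shape grid dims when `data` is scalar.
#' @export
sigma_field <- function(data, base_sigma, kind = c("stationary", "variable"),
                        shape = NULL) {
  kind <- match.arg(kind)
  if (length(data) == 1L && !is.null(shape)) data <- array(data, shape)
  stopifnot(length(dim(data)) == 3L, all(data >= 0), base_sigma >= 0)
  structure(list(data = data, base_sigma = base_sigma, kind = kind),
            class = "sigma_field")
}

#' Spatially variable sigma field (x3 in the centre)
#'
#' A 3x3x3 control lattice with value 3 at the central control point and 1
#' at every boundary control point is expanded to the full grid by
#' separable (tricubic) natural-spline interpolation and clamped to `>= 1`;
#' the field is `base_sigma` times that multiplier. The outermost voxels
#' therefore carry exactly `base_sigma`, and the centre `3 * base_sigma`
#' (27% of the intensity range when `base_sigma = 0.09`).
#'
#' @param shape integer dims, each `>= 3`.
#' @param base_sigma base sigma as a fraction of the unit intensity range.
#' @export
variable_sigma_field <- function(shape, base_sigma) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L), base_sigma >= 0)
  bump <- function(n) {
    t <- seq(0, 1, length.out = n)
    stats::spline(c(0, 0.5, 1), c(0, 1, 0), method = "natural", xout = t)$y
  }
  cx <- bump(shape[1]); cy <- bump(shape[2]); cz <- bump(shape[3])
  mult <- 1 + 2 * outer(outer(cx, cy), cz)
  mult <- pmax(mult, 1)
  dim(mult) <- shape
  sigma_field(base_sigma * mult, base_sigma, "variable")
}

#' Training noise regime
#'
#' `standard` draws the base sigma uniformly in [0%, 9%] of the intensity
#' range and pairs it with the spatially variable field; the refinement
#' regimes `refine_low` ([0%, 4%]) and `refine_high` ([4%, 9%]) use
#' stationary fields.
#' @param name one of "standard", "refine_low", "refine_high".
#' @export
noise_regime <- function(name = c("standard", "refine_low", "refine_high")) {
  name <- match.arg(name)
  r <- switch(name,
              standard = list(sigma_low = 0, sigma_high = 0.09,
                              field_kind = "variable"),
              refine_low = list(sigma_low = 0, sigma_high = 0.04,
                                field_kind = "stationary"),
              refine_high = list(sigma_low = 0.04, sigma_high = 0.09,
                                 field_kind = "stationary"))
  stopifnot(r$sigma_low >= 0, r$sigma_low <= r$sigma_high,
            r$sigma_high <= 0.09)
  structure(c(list(name = name), r), class = "noise_regime")
}

#' Draw base sigma values for a training regime
#'
#' Uniform on `[sigma_low, sigma_high]` (bounds inclusive), deterministic
#' given the seed.
#' @param regime a [noise_regime()].
#' @param seed integer seed.
#' @param n number of draws.
#' @export
sample_training_sigma <- function(regime, seed, n = 1L) {
  stopifnot(inherits(regime, "noise_regime"))
  if (regime$sigma_low == regime$sigma_high)
    return(rep(regime$sigma_low, n))
  rng_local(seed, function() stats::runif(n, regime$sigma_low, regime$sigma_high))
}

#' Add Rician noise to a volume
#'
#' Each voxel intensity A becomes `sqrt((A + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of that voxel's sigma. Sigma is a
#' fraction of the unit intensity range, so the input must be on the
#' conformed [0, 1] scale. The output magnitude can slightly exceed 1 and
#' is therefore marked `raw`.
#'
#' @param vol a unit-scale [volume()].
#' @param field a [sigma_field()] (shape-matched) or a scalar sigma.
#' @param seed integer seed; the noise is deterministic given it.
#' @export
add_rician <- function(vol, field, seed = 0L) {
  stopifnot(inherits(vol, "mri_volume"))
  if (vol$intensity_scale != "unit_0_1")
    stop("add_rician expects a unit-scale (conformed) volume")
  sg <- if (inherits(field, "sigma_field")) field$data else field
  if (length(sg) == 1L) sg <- array(sg, dim(vol$data))
  if (!identical(dim(sg), dim(vol$data)))
    stop("sigma field shape does not match the volume")
  n <- length(vol$data)
  noisy <- rng_local(seed, function() {
    n1 <- stats::rnorm(n) * sg
    n2 <- stats::rnorm(n) * sg
    sqrt((vol$data + n1)^2 + n2^2)
  })
  out <- volume(array(noisy, dim(vol$data)), vol$voxel_size, vol$orientation,
                "raw")
  if (inherits(vol, "conformed_volume")) {
    out$side <- vol$side; out$iso_voxel <- vol$iso_voxel
  }
  out
}
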