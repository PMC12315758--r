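# Image similarity metrics and reporting: MAE, MSE, PSNR, SSIM, MS-SSIM,
# deep-feature (L1) and LPIPS-style (L2) losses, Dice/IOU overlap, and
# paired statistical comparison with Benjamini-Hochberg FDR correction.

check_same_shape <- function(x, y) {
  if (!identical(dim(as.array(x)), dim(as.array(y))))
    stop("images must have identical shapes")
}

#' Mean absolute / mean squared error
#' @param x,y numeric arrays of identical shape.
#' @export
mae <- function(x, y) { check_same_shape(x, y); mean(abs(x - y)) }

#' @rdname mae
#' @export
mse <- function(x, y) { check_same_shape(x, y); mean((x - y)^2) }

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(MAXI^2 / MSE)`; identical images give `Inf`.
#' @param x,y images; `data_range` the maximum intensity MAXI.
#' @export
psnr <- function(x, y, data_range = 1.0) {
  check_same_shape(x, y)
  stopifnot(data_range > 0)
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(data_range^2 / m)
}

#' SSIM configuration
#'
#' @param k1,k2 stabilization constants (0.01 and 0.03).
#' @param L dynamic range (1.0 for unit-scale images, 255 for 8-bit).
#' @param window_size,window_sigma Gaussian local-statistics window
#'   (11x11, sigma 1.5).
#' @param msssim_weights the five per-scale exponents; when `M < 5` the
#'   first `M` are renormalized to sum to one.
#' @param M number of scales for MS-SSIM (default 2).
#' @export
ssim_config <- function(k1 = 0.01, k2 = 0.03, L = 1.0, window_size = 11L,
                        window_sigma = 1.5,
                        msssim_weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                        M = 2L) {
  stopifnot(k1 > 0, k2 > 0, L > 0, M >= 1, M <= 5, window_size %% 2L == 1L)
  structure(list(k1 = k1, k2 = k2, L = L, window_size = as.integer(window_size),
                 window_sigma = window_sigma, msssim_weights = msssim_weights,
                 M = as.integer(M)),
            class = "ssim_config")
}

gauss_window <- function(size, sigma) {
  t <- seq_len(size) - (size + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# Local-window statistics; returns the mean luminance map and the combined
# contrast-structure map of the SSIM index over valid windows.
ssim_maps <- function(x, y, config) {
  w <- gauss_window(config$window_size, config$window_sigma)
  if (nrow(x) < config$window_size || ncol(x) < config$window_size)
    stop("image smaller than the SSIM window")
  c1 <- (config$k1 * config$L)^2
  c2 <- (config$k2 * config$L)^2
  mx <- cpp_sepconv_valid(x, w); my <- cpp_sepconv_valid(y, w)
  sxx <- cpp_sepconv_valid(x * x, w) - mx^2
  syy <- cpp_sepconv_valid(y * y, w) - my^2
  sxy <- cpp_sepconv_valid(x * y, w) - mx * my
  lum <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cs <- (2 * sxy + c2) / (sxx + syy + c2)
  list(lum = lum, cs = cs)
}

as_slice_list <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2L) return(list(x))
  lapply(seq_len(dim(x)[3]), function(k) x[, , k])
}

#' Structural similarity index
#'
#' Mean over sliding Gaussian windows of the SSIM index with
#' `c1 = (k1 L)^2`, `c2 = (k2 L)^2`. 3D inputs are scored slice-wise
#' (third axis) and averaged.
#' @param x,y images on the configured dynamic range.
#' @param config an [ssim_config()].
#' @export
ssim <- function(x, y, config = ssim_config()) {
  check_same_shape(x, y)
  vals <- mapply(function(a, b) {
    m <- ssim_maps(a, b, config)
    mean(m$lum * m$cs)
  }, as_slice_list(x), as_slice_list(y))
  mean(vals)
}

#' Multi-scale structural similarity
#'
#' Contrast-structure terms at scales `1..M-1` (each scale a 2x
#' average-pool of the previous) and the full SSIM (luminance included) at
#' the coarsest scale, combined with the configured exponents (renormalized
#' to sum to one when `M < 5`). With `M = 1` this reduces exactly to
#' single-scale SSIM. Negative per-scale terms are clamped at zero before
#' exponentiation.
#' @inheritParams ssim
#' @export
msssim <- function(x, y, config = ssim_config()) {
  check_same_shape(x, y)
  wts <- config$msssim_weights[seq_len(config$M)]
  wts <- wts / sum(wts)
  score_pair <- function(a, b) {
    need <- config$window_size * 2^(config$M - 1L)
    if (min(dim(a)) < need)
      stop("image too small for ", config$M, " MS-SSIM scales")
    terms <- numeric(config$M)
    for (j in seq_len(config$M)) {
      m <- ssim_maps(a, b, config)
      terms[j] <- if (j == config$M) max(mean(m$lum * m$cs), 0)
      else max(mean(m$cs), 0)
      if (j < config$M) { a <- down2(a); b <- down2(b) }
    }
    prod(terms^wts)
  }
  vals <- mapply(score_pair, as_slice_list(x), as_slice_list(y))
  mean(vals)
}

down2 <- function(x) {
  h <- 2L * (nrow(x) %/% 2L); w <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
            x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)])
}

# ---- deep-feature similarity ---------------------------------------------

#' Convolutional feature extractor for perceptual losses
#'
#' A small stack of seeded 3x3 convolution + ReLU layers. The default
#' `fixed_random_seeded` origin is fully deterministic and self-contained;
#' random convolutional features are a recognized test double for deep
#' perceptual metrics. Pretrained classifier weights are not bundled, so
#' `origin = "pretrained_classifier"` raises an error instructing the
#' fallback.
#'
#' @param origin "fixed_random_seeded" or "pretrained_classifier".
#' @param seed weight seed.
#' @param n_filt filters per layer.
#' @param n_layers number of convolutional layers available.
#' @param layers which layers enter the loss (default the first).
#' @export
feature_extractor <- function(origin = c("fixed_random_seeded",
                                         "pretrained_classifier"),
                              seed = 0L, n_filt = 16L, n_layers = 2L,
                              layers = 1L) {
  origin <- match.arg(origin)
  if (origin == "pretrained_classifier")
    stop("pretrained classifier weights are not bundled with this package; ",
         "use origin = 'fixed_random_seeded' for a deterministic extractor")
  stopifnot(all(layers >= 1L), all(layers <= n_layers))
  ws <- rng_local(seed, function() {
    out <- list(conv_init(3L, n_filt, 3L))
    for (l in seq_len(n_layers - 1L))
      out <- c(out, list(conv_init(n_filt, n_filt, 3L)))
    out
  })
  structure(list(origin = origin, seed = as.integer(seed), weights = ws,
                 n_layers = as.integer(n_layers), layers = as.integer(layers)),
            class = "feature_extractor")
}

# Feature maps Phi_l for a grayscale image (channel-replicated to 3).
extract_features <- function(extractor, x) {
  if (!inherits(extractor, "feature_extractor"))
    stop("extractor is not initialized")
  h <- array(rep(as.numeric(x), 3L), c(dim(as.array(x))[1:2], 3L))
  out <- vector("list", extractor$n_layers)
  for (l in seq_len(extractor$n_layers)) {
    cv <- extractor$weights[[l]]
    h <- nval(t_relu(t_conv2d(new_node(h, leaf = TRUE), cv$w, cv$b)))
    out[[l]] <- h
  }
  out
}

#' Deep-feature L1 loss
#'
#' Mean absolute difference of the selected feature maps:
#' `(1/N_l) sum |Phi_l(x) - Phi_l(y)|`, averaged over the configured layers.
#' @param x,y grayscale images.
#' @param extractor a [feature_extractor()].
#' @export
feature_loss <- function(x, y, extractor = feature_extractor()) {
  check_same_shape(x, y)
  fx <- extract_features(extractor, x)
  fy <- extract_features(extractor, y)
  mean(vapply(extractor$layers, function(l) mean(abs(fx[[l]] - fy[[l]])), 0))
}

#' LPIPS-style deep-feature L2 similarity
#'
#' Per-layer mean squared feature difference, averaged over the configured
#' layers. With the seeded extractor this is a deterministic perceptual
#' distance; lower is more similar.
#' @inheritParams feature_loss
#' @export
lpips_like <- function(x, y, extractor = feature_extractor()) {
  check_same_shape(x, y)
  fx <- extract_features(extractor, x)
  fy <- extract_features(extractor, y)
  mean(vapply(extractor$layers, function(l) mean((fx[[l]] - fy[[l]])^2), 0))
}

#' Dice and intersection-over-union overlap
#'
#' `dice = 2|A n B| / (|A| + |B|)`, `iou = |A n B| / |A u B|`; both are
#' defined as 1 when both masks are empty.
#' @param maskA,maskB binary (0/1 or logical) arrays of identical shape.
#' @export
dice_iou <- function(maskA, maskB) {
  check_same_shape(maskA, maskB)
  a <- as.numeric(maskA); b <- as.numeric(maskB)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("dice_iou expects binary masks")
  inter <- sum(a * b); sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(c(dice = 1, iou = 1))
  un <- sa + sb - inter
  c(dice = 2 * inter / (sa + sb), iou = if (un == 0) 1 else inter / un)
}

#' All similarity metrics for one image pair
#'
#' @param x,y images on the unit scale.
#' @param config an [ssim_config()].
#' @param extractor a [feature_extractor()].
#' @export
similarity_metrics <- function(x, y, config = ssim_config(),
                               extractor = feature_extractor()) {
  feats <- if (length(dim(as.array(x))) == 2L) {
    c(feature = feature_loss(x, y, extractor),
      lpips = lpips_like(x, y, extractor))
  } else {
    mid <- dim(as.array(x))[3] %/% 2L + 1L
    c(feature = feature_loss(as.array(x)[, , mid], as.array(y)[, , mid], extractor),
      lpips = lpips_like(as.array(x)[, , mid], as.array(y)[, , mid], extractor))
  }
  c(mae = mae(x, y), mse = mse(x, y), psnr = psnr(x, y, config$L),
    ssim = ssim(x, y, config), msssim = msssim(x, y, config), feats)
}

# ---- paired comparison reporting -----------------------------------------

#' Paired comparison of methods against a reference
#'
#' Paired t-tests of each method's per-image metric values against the
#' reference method, with Benjamini-Hochberg step-up FDR correction.
#' Methods are labelled `better` / `worse` / `ns` at `q < 0.05`; a method
#' identical to the reference is `ns` with p = 1.
#'
#' @param values_by_method a numeric matrix or data.frame with one row per
#'   image and one named column per method, or a long data.frame with
#'   columns `image`, `method`, `value`.
#' @param reference reference method name.
#' @param higher_better direction in which the metric improves.
#' @return object of class `metric_report`.
#' @export
paired_compare <- function(values_by_method, reference, higher_better = TRUE) {
  tb <- values_by_method
  if (is.data.frame(tb) && all(c("image", "method", "value") %in% names(tb))) {
    wide <- stats::reshape(tb[, c("image", "method", "value")],
                           idvar = "image", timevar = "method",
                           direction = "wide")
    rownames(wide) <- wide$image
    wide$image <- NULL
    names(wide) <- sub("^value\\.", "", names(wide))
    tb <- wide
  }
  tb <- as.matrix(tb)
  if (anyNA(tb)) stop("paired_compare: unbalanced pairing (missing values)")
  if (!reference %in% colnames(tb)) stop("unknown reference method: ", reference)
  if (ncol(tb) < 2L) stop("need at least two methods")
  if (nrow(tb) < 3L) stop("need at least three paired observations")
  ref <- tb[, reference]
  methods <- setdiff(colnames(tb), reference)
  rows <- lapply(methods, function(m) {
    d <- tb[, m] - ref
    if (all(d == 0)) {
      data.frame(method = m, n = length(d), mean = mean(tb[, m]),
                 sd = stats::sd(tb[, m]), delta = 0, t = NA_real_, p = 1)
    } else if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
      # constant nonzero shift: zero-variance differences, unboundedly
      # significant under the paired t model
      data.frame(method = m, n = length(d), mean = mean(tb[, m]),
                 sd = stats::sd(tb[, m]), delta = mean(d),
                 t = sign(mean(d)) * Inf, p = 0)
    } else {
      tt <- stats::t.test(tb[, m], ref, paired = TRUE)
      data.frame(method = m, n = length(d), mean = mean(tb[, m]),
                 sd = stats::sd(tb[, m]), delta = mean(d),
                 t = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  improves <- if (higher_better) out$delta > 0 else out$delta < 0
  out$label <- ifelse(out$q < 0.05, ifelse(improves, "better", "worse"), "ns")
  structure(list(table = out, reference = reference,
                 higher_better = higher_better),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Paired comparison vs reference:", x$reference, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Export a metric report as CSV or JSON
#' @param report a `metric_report`.
#' @param path output file.
#' @param format "csv" or "json" (default from the extension).
#' @export
export_metric_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (is.null(format))
    format <- if (grepl("\\.json$", tolower(path))) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(report$table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(reference = report$reference,
                              table = report$table),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
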