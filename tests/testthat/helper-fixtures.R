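# Shared fixtures and independent oracles used across the suite.

tiny_phantom <- function(seed = 7L, shape = c(24L, 24L, 24L),
                         voxel = c(1, 1, 1)) {
  make_phantom(phantom_spec(shape = shape, voxel_size = voxel, seed = seed))
}

rand_img <- function(seed, h = 32L, w = h) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Brute-force SSIM: explicit per-window statistics with the same Gaussian
# weights, independent of the separable-convolution implementation.
ssim_oracle <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1, win = 11L,
                        sigma = 1.5) {
  t <- seq_len(win) - (win + 1) / 2
  w1 <- exp(-t^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1L)) {
    for (j in seq_len(ncol(x) - win + 1L)) {
      px <- x[i:(i + win - 1L), j:(j + win - 1L)]
      py <- y[i:(i + win - 1L), j:(j + win - 1L)]
      mx <- sum(W * px); my <- sum(W * py)
      vx <- sum(W * px^2) - mx^2; vy <- sum(W * py^2) - my^2
      cxy <- sum(W * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Direct dense 3x3 convolution (+ReLU) oracle for the feature extractor.
conv3_relu_oracle <- function(x, Wm, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- nrow(Wm)
  out <- array(0, c(H, W, Cout))
  xp <- array(0, c(H + 2L, W + 2L, Cin))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (dj in 0:2) for (di in 0:2) {
        wv <- Wm[co, (ci - 1L) * 9L + dj * 3L + di + 1L]
        acc <- acc + wv * xp[(1:H) + di, (1:W) + dj, ci]
      }
    }
    out[, , co] <- pmax(acc, 0)
  }
  out
}

feature_maps_oracle <- function(extractor, img) {
  h <- array(rep(as.numeric(img), 3L), c(dim(img), 3L))
  out <- list()
  for (l in seq_len(extractor$n_layers)) {
    cv <- extractor$weights[[l]]
    h <- conv3_relu_oracle(h, cv$w$v, as.numeric(cv$b$v))
    out[[l]] <- h
  }
  out
}

# A small slab of random data for architecture tests.
rand_slab <- function(seed, h = 32L, w = h, c = 7L) {
  set.seed(seed)
  array(runif(h * w * c), c(h, w, c))
}
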