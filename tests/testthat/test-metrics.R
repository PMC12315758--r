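test_that("MAE, MSE and PSNR follow their closed forms", {
  x <- rand_img(1)
  expect_equal(mae(x, x), 0)
  expect_equal(mse(x, x), 0)
  expect_equal(mae(x, x + 0.25), 0.25)
  expect_equal(mse(x, x + 0.25), 0.0625)
  y <- rand_img(2)
  expect_lt(abs(mae(x, y) - mean(abs(as.numeric(x) - as.numeric(y)))), 1e-7)
  expect_lt(abs(mse(x, y) - mean((as.numeric(x) - as.numeric(y))^2)), 1e-7)
  expect_identical(psnr(x, x), Inf)
  a <- matrix(0, 8, 8)
  expect_equal(psnr(a, a + 128, 255), 20 * log10(255 / 128))
  expect_equal(psnr(x, y, 1), psnr(7 * x, 7 * y, 7))
  expect_error(mae(x, y[1:10, ]), "shapes")
})

test_that("SSIM matches a brute-force sliding-window oracle and its axioms", {
  x <- rand_img(3); y <- rand_img(4)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lte(ssim(x, y), 1 + 1e-9)
  expect_lt(abs(ssim(x, y) - ssim_oracle(x, y)), 1e-6)
  expect_error(ssim(x[1:8, 1:8], y[1:8, 1:8]), "window")
})

test_that("MS-SSIM composes per-scale terms correctly", {
  x <- rand_img(5, 64L); y <- x + matrix(rnorm(64 * 64, sd = 0.05), 64)
  expect_equal(msssim(x, x), 1)
  cfg1 <- ssim_config(M = 1L)
  expect_lt(abs(msssim(x, y, cfg1) - ssim(x, y)), 1e-6)
  # compositional oracle at M = 2: cs mean at full scale, full SSIM at the
  # 2x-downsampled scale, with the renormalized printed exponents
  cfg2 <- ssim_config(M = 2L)
  w <- c(0.0448, 0.2856); w <- w / sum(w)
  win <- mridenoise:::gauss_window(11L, 1.5)
  cs_mean <- function(a, b) {
    m <- mridenoise:::ssim_maps(a, b, cfg2)
    mean(m$cs)
  }
  d2 <- mridenoise:::down2
  oracle <- cs_mean(x, y)^w[1] * ssim(d2(x), d2(y))^w[2]
  expect_lt(abs(msssim(x, y, cfg2) - oracle), 1e-6)
  expect_error(msssim(x[1:16, 1:16], y[1:16, 1:16], cfg2), "small")
})

test_that("feature and LPIPS-style losses match the direct formula oracle", {
  fe <- feature_extractor(seed = 5L)
  x <- rand_img(6); y <- rand_img(7)
  expect_equal(feature_loss(x, x, fe), 0)
  expect_equal(lpips_like(x, x, fe), 0)
  expect_gte(feature_loss(x, y, fe), 0)
  expect_equal(lpips_like(x, y, fe), lpips_like(y, x, fe))
  fx <- feature_maps_oracle(fe, x)
  fy <- feature_maps_oracle(fe, y)
  expect_lt(abs(feature_loss(x, y, fe) - mean(abs(fx[[1]] - fy[[1]]))), 1e-6)
  expect_lt(abs(lpips_like(x, y, fe) - mean((fx[[1]] - fy[[1]])^2)), 1e-6)
  expect_error(feature_extractor(origin = "pretrained_classifier"),
               "fixed_random_seeded")
})

test_that("Dice and IOU overlap values are exact", {
  a <- array(0L, c(4, 4)); b <- a
  a[1:2, 1] <- 1L; b[2:3, 1] <- 1L  # |A|=|B|=2, overlap 1
  expect_equal(dice_iou(a, b), c(dice = 1 / 2, iou = 1 / 3))
  # dice and iou are linked by d = 2i/(1+i)
  i <- dice_iou(a, b)[["iou"]]
  expect_equal(dice_iou(a, b)[["dice"]], 2 * i / (1 + i))
  expect_equal(dice_iou(a, a), c(dice = 1, iou = 1))
  disj <- array(0L, c(4, 4)); disj[4, 4] <- 1L
  expect_equal(dice_iou(a, disj), c(dice = 0, iou = 0))
  empty <- array(0L, c(4, 4))
  expect_equal(dice_iou(empty, empty), c(dice = 1, iou = 1))
  expect_error(dice_iou(a * 2, b), "binary")
})

test_that("paired comparison labels methods and corrects with BH", {
  set.seed(8)
  ref <- rnorm(20, 10, 1)
  tbl <- cbind(reference = ref,
               same = ref,
               shifted = ref + 10,   # 10 sigma shift
               noisy = ref + rnorm(20, 0, 1e-4))
  rep <- paired_compare(tbl, "reference")
  t_same <- rep$table[rep$table$method == "same", ]
  expect_equal(t_same$p, 1)
  expect_identical(t_same$label, "ns")
  t_shift <- rep$table[rep$table$method == "shifted", ]
  expect_lt(t_shift$q, 0.05)
  expect_identical(t_shift$label, "better")
  t_noisy <- rep$table[rep$table$method == "noisy", ]
  expect_identical(t_noisy$label, "ns")
  # q-values are monotone under the step-up procedure
  expect_true(all(diff(rep$table$q[order(rep$table$p)]) >= 0))
  # BH arithmetic
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # long-format input and export
  long <- data.frame(image = rep(seq_len(20), 2),
                     method = rep(c("reference", "shifted"), each = 20),
                     value = c(ref, ref + 10))
  rep2 <- paired_compare(long, "reference")
  expect_equal(rep2$table$delta, 10, tolerance = 1e-9)
  f <- tempfile(fileext = ".csv")
  export_metric_report(rep2, f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), 1L)
  unlink(f)
  expect_error(paired_compare(tbl[1:2, ], "reference"), "three")
})

test_that("PSNR and SSIM degrade monotonically with the noise level", {
  ph <- conform(tiny_phantom(10L, shape = c(32L, 32L, 32L)))
  sl <- ph$data
  res <- sapply(c(0.01, 0.05, 0.09), function(s) {
    ps <- sapply(1:3, function(r) {
      nz <- add_rician(ph, s, seed = 100L * r + round(1000 * s))
      c(psnr(nz$data, sl), ssim(nz$data[, , 16], sl[, , 16]))
    })
    rowMeans(ps)
  })
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
})
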