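test_that("maxout is an exact elementwise maximum", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_identical(maxout(x, x), x)
  expect_identical(maxout(x, x + 1), x + 1)
  y <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  oracle <- array(mapply(max, x, y), dim(x))
  expect_identical(maxout(x, y), oracle)
  expect_error(maxout(x, y[, , 1:2]), "shape")
})

test_that("vinn_rescale scales by R_o/R_i and inverts exactly", {
  set.seed(2)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  expect_identical(dim(vinn_rescale(x, 1, 1)), dim(x))
  half <- vinn_rescale(x, R_o = 0.5, R_i = 1.0)
  expect_identical(dim(half)[1:2], c(32L, 32L))
  back <- vinn_rescale(half, R_o = 0.5, R_i = 1.0, direction = "to_native")
  expect_identical(dim(back), dim(x))
  # non-integer factor still round-trips through the stored native dims
  odd <- vinn_rescale(x, R_o = 0.7, R_i = 1.0)
  expect_identical(dim(vinn_rescale(odd, 0.7, 1.0, "to_native"))[1:2],
                   c(64L, 64L))
  expect_error(vinn_rescale(x, R_o = 0.01, R_i = 1.0), "too small")
})

test_that("CBU blocks preserve spatial shape and collapse output heads", {
  cfg <- network_config(n_filt = 6L)
  set.seed(3)
  x <- array(rnorm(20 * 24 * 7), c(20, 24, 7))
  bi <- cbu_init(cfg, "input")
  expect_identical(dim(cbu_forward(x, bi)), c(20L, 24L, 6L))
  f <- array(rnorm(20 * 24 * 6), c(20, 24, 6))
  bs <- cbu_init(cfg, "standard")
  expect_identical(dim(cbu_forward(f, bs)), c(20L, 24L, 6L))
  bo <- cbu_init(cfg, "output")
  expect_identical(dim(cbu_forward(f, bo)), c(20L, 24L, 1L))
  expect_error(cbu_forward(x[, , 1:3], bi), "channels")
  # batch-norm toggle changes only the normalization parameter count
  cfg_bn <- network_config(n_filt = 6L, use_batchnorm = TRUE)
  b1 <- cbu_init(cfg, "standard"); b2 <- cbu_init(cfg_bn, "standard")
  expect_equal(count_params(b2) - count_params(b1), 3L * 2L * 6L)
  conv_count <- function(b) sum(vapply(c("conv1", "conv2", "conv3"),
                                       function(nm) length(b[[nm]]$w$v) +
                                         length(b[[nm]]$b$v), 0))
  expect_equal(conv_count(b1), conv_count(b2))
})

test_that("the nested denoiser satisfies its structural contracts", {
  cfg <- network_config(n_filt = 4L)
  net <- build_nested_denoiser(cfg, seed = 1)
  # 7-row layout: 6 candidate heads, shape preserved
  x <- rand_slab(1, 32L)
  cands <- mridenoise:::net_forward(net, x, R_o = 1.0)
  expect_length(cands, 6L)
  for (cc in cands)
    expect_identical(dim(mridenoise:::nval(cc)), c(32L, 32L, 1L))
  # input channel count is enforced
  expect_error(denoise_slab(net, slab_batch(array(0, c(1, 5, 32, 32)))),
               "channels")
  # parameter-count determinism
  expect_identical(count_params(build_nested_denoiser(cfg, seed = 9)),
                   count_params(net))
  # identical weights => identical outputs
  net2 <- build_nested_denoiser(cfg, seed = 1)
  c2 <- mridenoise:::net_forward(net2, x, R_o = 1.0)
  expect_identical(mridenoise:::nval(cands[[4]]), mridenoise:::nval(c2[[4]]))
  # lambda initialized to 1
  expect_identical(as.numeric(net$lambdas$v), rep(1, 6))
  # filter doubling doubles per pooled row
  cfgd <- network_config(n_filt = 4L, filter_doubling = TRUE)
  netd <- build_nested_denoiser(cfgd, seed = 1)
  expect_equal(netd$blocks[["b2_0"]]$c_out, 8L)
  expect_equal(netd$blocks[["b6_0"]]$c_out, 4L * 2L^5L)
  expect_equal(netd$blocks[["b0_1"]]$c_out, 4L)
  cd <- mridenoise:::net_forward(netd, x, R_o = 1.0)
  expect_identical(dim(mridenoise:::nval(cd[[1]])), c(32L, 32L, 1L))
})

test_that("combine_candidates is the lambda-weighted mean", {
  set.seed(4)
  ys <- lapply(1:6, function(i) matrix(rnorm(16), 4))
  same <- lapply(1:6, function(i) ys[[1]])
  expect_equal(combine_candidates(same, rep(2.5, 6)), ys[[1]])
  expect_equal(combine_candidates(ys, c(1, 0, 0, 0, 0, 0)), ys[[1]])
  lam <- rnorm(6)
  oracle <- Reduce(`+`, Map(`*`, ys, as.list(lam))) / sum(lam)
  expect_lt(max(abs(combine_candidates(ys, lam) - oracle)), 1e-6)
  expect_equal(combine_candidates(list(Y = ys, lambdas = lam)), oracle)
  expect_error(combine_candidates(ys, c(1, -1, 1, -1, 1, -1)), "degenerate")
})

test_that("zeroed output heads give an identity denoiser (all architectures)", {
  x <- rand_slab(5, 32L)
  sb <- slab_batch(array(aperm(x, c(3, 1, 2)), c(1, 7, 32, 32)))
  for (net in list(build_nested_denoiser(network_config(n_filt = 4L), 1),
                   build_mcdncnn(network_config(n_filt = 8L), 1),
                   build_unet_vinn(network_config(n_filt = 4L), 1))) {
    zero_residual(net)
    out <- denoise_slab(net, sb)
    expect_equal(out[1, , ], x[, , 4], tolerance = 1e-12)
  }
})

test_that("denoise_slab preserves shape across sizes and native resolutions", {
  net <- build_nested_denoiser(network_config(n_filt = 4L), seed = 2)
  for (hw in c(32L, 48L)) {
    for (ro in c(0.7, 1.2)) {
      x <- rand_slab(hw + ro * 10, hw)
      sb <- slab_batch(array(aperm(x, c(3, 1, 2)), c(1, 7, hw, hw)),
                       native_res = ro)
      expect_identical(dim(denoise_slab(net, sb)), c(1L, hw, hw))
    }
  }
})

test_that("comparator architectures match their published layouts", {
  m <- build_mcdncnn(network_config(n_filt = 64L), seed = 1)
  expect_length(m$layers, 17L)
  for (l in 2:16) expect_equal(nrow(m$layers[[l]]$conv$w$v), 64L)
  expect_equal(nrow(m$layers[[17]]$conv$w$v), 1L)
  u <- build_unet_vinn(network_config(n_filt = 32L), seed = 1)
  expect_equal(u$n_levels, 5L)
  expect_equal(u$enc[[5]]$c_out, 512L)
  expect_equal(u$input$c_out, 32L)
  # forward shape preservation
  u8 <- build_unet_vinn(network_config(n_filt = 4L), seed = 1)
  x <- rand_slab(6, 48L)
  out <- mridenoise:::net_forward(u8, x, R_o = 1.0)
  expect_identical(dim(mridenoise:::nval(out[[1]])), c(48L, 48L, 1L))
})

test_that("checkpoints restore a bit-identical forward pass", {
  net <- build_nested_denoiser(network_config(n_filt = 4L), seed = 3)
  x <- rand_slab(7, 32L)
  sb <- slab_batch(array(aperm(x, c(3, 1, 2)), c(1, 7, 32, 32)))
  out1 <- denoise_slab(net, sb)
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_identical(denoise_slab(net2, sb), out1)
  unlink(f)
})
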