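test_that("the one-cycle schedule ramps to max_lr and anneals to the floor", {
  lrs <- one_cycle_lr(0:9999, 10000)
  expect_equal(lrs[1], 0.001)          # max_lr / div_factor
  expect_equal(max(lrs), 0.01)         # peak = max_lr
  expect_equal(which.max(lrs) - 1L, 750L)  # attained at pct_start * total
  expect_equal(lrs[10000], 1e-5)       # initial / final_div_factor
  expect_error(one_cycle_lr(0, 1), "at least 2")
  expect_error(one_cycle_lr(10, 10), "")
})

test_that("a toy run converges, is deterministic, and trains the lambdas", {
  cfg_net <- network_config(n_filt = 4L, rows = 4L, candidates = 3L)
  vols <- lapply(1:2, function(i)
    make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 50L + i)))
  tc <- train_config(variant = "base_lpips", loss = "mae", epochs = 2L,
                     steps_per_epoch = 15L, batch_size = 2L, seed = 0L,
                     crop_size = 16L)
  net <- build_nested_denoiser(cfg_net, seed = 0L)
  lam0 <- as.numeric(net$lambdas$v)
  fit <- train_denoiser(net, vols, tc)
  tr <- fit$trace
  expect_equal(nrow(tr), 30L)
  expect_lt(mean(tr$loss[tr$epoch == 2]), mean(tr$loss[tr$epoch == 1]))
  # lambdas received gradient updates
  expect_false(identical(as.numeric(fit$model$lambdas$v), lam0))
  # determinism: identical seeds give identical traces
  net_b <- build_nested_denoiser(cfg_net, seed = 0L)
  fit_b <- train_denoiser(net_b, vols, tc)
  expect_identical(fit_b$trace$loss, tr$loss)
})

test_that("gradients reach all six candidate weights", {
  net <- build_nested_denoiser(network_config(n_filt = 4L), seed = 4)
  x <- rand_slab(9, 32L)
  mridenoise:::tg_start()
  cands <- mridenoise:::net_forward(net, x, 1.0, training = TRUE)
  Y <- mridenoise:::t_combine(cands, net$lambdas)
  den <- mridenoise:::t_sub(mridenoise:::new_node(x[, , 4, drop = FALSE],
                                                  leaf = TRUE), Y)
  loss <- mridenoise:::t_mean_abs(den, array(0, c(32, 32, 1)))
  mridenoise:::tg_backward(loss)
  mridenoise:::tg_stop()
  expect_length(net$lambdas$g, 6L)
  expect_true(all(abs(net$lambdas$g) > 0))
  mridenoise:::zero_grads(net$par_list)
})

test_that("mixed precision changes no shapes and barely moves the toy loss", {
  cfg_net <- network_config(n_filt = 4L, rows = 4L, candidates = 3L)
  vols <- list(make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 60L)))
  run <- function(mp) {
    tc <- train_config(variant = "base_lpips", loss = "mae", epochs = 1L,
                       steps_per_epoch = 10L, batch_size = 1L, seed = 1L,
                       crop_size = 16L, mixed_precision = mp)
    fit <- train_denoiser(build_nested_denoiser(cfg_net, seed = 1L), vols, tc)
    utils::tail(fit$trace$loss, 1)
  }
  l_full <- run(FALSE); l_mixed <- run(TRUE)
  expect_lt(abs(l_mixed - l_full) / l_full, 0.1)
})

test_that("refinement variants require and use a frozen first stage", {
  cfg_net <- network_config(n_filt = 4L, rows = 4L, candidates = 3L)
  vols <- list(make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 70L)))
  tc <- train_config(variant = "refine_low", loss = "mae", epochs = 1L,
                     steps_per_epoch = 2L, batch_size = 1L, seed = 2L,
                     crop_size = 16L)
  net <- build_nested_denoiser(cfg_net, seed = 2L)
  expect_error(train_denoiser(net, vols, tc), "first-stage")
  first <- zero_residual(build_nested_denoiser(cfg_net, seed = 3L))
  fit <- train_denoiser(net, vols, tc, first_stage = first)
  expect_true(all(is.finite(fit$trace$loss)))
  # the fixed refinement learning rate is used
  expect_true(all(fit$trace$lr == 1e-6))
})

test_that("feature-based losses backpropagate through the extractor", {
  cfg_net <- network_config(n_filt = 4L, rows = 4L, candidates = 3L)
  vols <- list(make_phantom(phantom_spec(shape = c(32L, 32L, 32L), seed = 80L)))
  for (lo in c("feature_loss_l1", "lpips_like")) {
    tc <- train_config(variant = "base_feat", loss = lo, epochs = 1L,
                       steps_per_epoch = 3L, batch_size = 1L, seed = 3L,
                       crop_size = 16L)
    fit <- train_denoiser(build_nested_denoiser(cfg_net, seed = 4L), vols, tc)
    expect_true(all(is.finite(fit$trace$loss)))
  }
})
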