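test_that("slab extraction covers every slice with edge replication", {
  cv <- conform(tiny_phantom(20L, shape = c(20L, 20L, 20L)))
  for (pl in c("axial", "coronal", "sagittal")) {
    ps <- extract_slabs(cv, pl)
    expect_equal(dim(ps$slabs)[1], 20L)   # one slab per slice
    expect_equal(dim(ps$slabs)[2], 7L)
  }
  ps <- extract_slabs(cv, "axial")
  # middle channel of slab k is slice k
  for (k in c(1L, 9L, 20L))
    expect_identical(ps$slabs[k, 4, , ], cv$data[, , k])
  # at k = 1 channels 1..3 replicate slice 1
  for (c in 1:3) expect_identical(ps$slabs[1, c, , ], cv$data[, , 1])
  # at k = S channels 5..7 replicate slice S
  for (c in 5:7) expect_identical(ps$slabs[20, c, , ], cv$data[, , 20])
  small <- conform(tiny_phantom(21L, shape = c(5L, 5L, 5L)))
  expect_error(extract_slabs(small, "axial"), "at least")
})

test_that("a zero-residual network leaves every plane and the pipeline unchanged", {
  net <- zero_residual(build_nested_denoiser(network_config(n_filt = 4L), 1))
  cv <- conform(tiny_phantom(22L, shape = c(24L, 24L, 24L)))
  for (pl in c("axial", "coronal", "sagittal")) {
    out <- denoise_plane(net, cv, pl)
    expect_equal(out$data, cv$data, tolerance = 1e-12)
  }
  full <- denoise_volume(net, cv)
  expect_equal(full$data, cv$data, tolerance = 1e-12)
  # and through a debug checkpoint round trip
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(net, f)
  full2 <- denoise_volume(load_checkpoint(f), cv)
  expect_identical(full2$data, full$data)
  unlink(f)
})

test_that("per-slab results are independent of the batch partition", {
  net <- build_nested_denoiser(network_config(n_filt = 4L), seed = 5)
  cv <- conform(tiny_phantom(23L, shape = c(24L, 24L, 24L)))
  o1 <- denoise_plane(net, cv, "axial", batch_size = 1L)
  o8 <- denoise_plane(net, cv, "axial", batch_size = 8L)
  expect_identical(o1$data, o8$data)
})

test_that("view aggregation is the symmetric voxelwise mean", {
  set.seed(24)
  a <- array(runif(6^3), c(6, 6, 6))
  b <- array(runif(6^3), c(6, 6, 6))
  c3 <- array(runif(6^3), c(6, 6, 6))
  expect_identical(view_aggregate(a, a, a), a)
  expect_equal(view_aggregate(a, b, c3), view_aggregate(c3, a, b))
  expect_lt(max(abs(view_aggregate(a, b, c3) - (a + b + c3) / 3)), 1e-7)
  # never exceeds the per-voxel max of its inputs
  expect_true(all(view_aggregate(a, b, c3) <= pmax(a, b, c3) + 1e-12))
  expect_error(view_aggregate(a, b, c3[1:3, , ]), "shape")
})

test_that("denoise_volume is deterministic and clamps to [0, 1]", {
  net <- build_nested_denoiser(network_config(n_filt = 4L), seed = 6)
  cv <- conform(tiny_phantom(25L, shape = c(24L, 24L, 24L)))
  o1 <- denoise_volume(net, cv)
  o2 <- denoise_volume(net, cv)
  expect_identical(o1$data, o2$data)
  expect_gte(min(o1$data), 0)
  expect_lte(max(o1$data), 1)
  expect_identical(dim(o1$data), dim(cv$data))
})
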