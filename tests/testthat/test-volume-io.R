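test_that("NIfTI and MGH round-trips preserve data, voxel sizes and orientation", {
  ph <- tiny_phantom(1L, voxel = c(1, 1.1, 1.2))
  for (ext in c(".nii.gz", ".nii", ".mgz", ".mgh")) {
    f <- tempfile(fileext = ext)
    write_volume(ph, f)
    r <- read_volume(f)
    expect_lt(max(abs(r$data - ph$data)), 1e-6)  # stored as float
    expect_equal(r$voxel_size, ph$voxel_size, tolerance = 1e-6)
    expect_identical(r$orientation, "RAS")
    unlink(f)
  }
})

test_that("the reader preserves non-RAS header orientations untouched", {
  ph <- tiny_phantom(2L)
  v <- volume(ph$data, c(1, 1, 1), "LPS", "unit_0_1")
  for (ext in c(".nii.gz", ".mgz")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    expect_identical(read_volume(f)$orientation, "LPS")
    unlink(f)
  }
})

test_that("unreadable, truncated, and unsupported files raise clear errors", {
  expect_error(read_volume("/no/such/file.nii"), "no such file")
  expect_error(read_volume(tempfile(fileext = ".xyz")), "")
  f <- tempfile(fileext = ".mgh")
  write_volume(tiny_phantom(3L), f)
  raw <- readBin(f, "raw", n = file.info(f)$size)
  writeBin(raw[1:400], f)
  expect_error(read_volume(f), "truncated")
  expect_error(write_volume(tiny_phantom(3L), tempfile(fileext = ".xyz")),
               "unsupported")
  unlink(f)
})

test_that("to_ras maps orientations correctly (coordinate oracle)", {
  # RAS input is untouched
  v <- volume(tiny_phantom(4L)$data, c(1, 1, 1), "RAS", "unit_0_1")
  expect_identical(to_ras(v)$data, v$data)
  # LPS: two axis flips, idempotent
  vl <- volume(v$data, c(1, 1, 1.2), "LPS", "unit_0_1")
  r1 <- to_ras(vl)
  expect_identical(r1$orientation, "RAS")
  expect_identical(r1$data, to_ras(r1)$data)
  expect_identical(r1$data,
                   v$data[rev(seq_len(24)), rev(seq_len(24)), , drop = FALSE])
  # random permuted orientations: a marked voxel lands where a brute-force
  # world-coordinate mapping predicts
  codes <- c("PIR", "SLP", "IAL", "ASR")
  for (code in codes) {
    d <- array(0, c(6L, 8L, 10L))
    mark <- c(2L, 3L, 4L)
    d[mark[1], mark[2], mark[3]] <- 1
    vv <- volume(d, c(1, 2, 3), code, "raw")
    rr <- to_ras(vv)
    # oracle: world axis and sign of each source axis
    lets <- strsplit(code, "")[[1]]
    ax <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)[lets]
    pos <- lets %in% c("R", "A", "S")
    expected_idx <- integer(3)
    for (t in 1:3) {
      k <- which(ax == t)
      expected_idx[t] <- if (pos[k]) mark[k] else dim(d)[k] - mark[k] + 1L
    }
    expect_equal(which(rr$data == 1, arr.ind = TRUE)[1, ],
                 expected_idx, ignore_attr = TRUE)
    expect_equal(rr$voxel_size, c(1, 2, 3)[match(1:3, ax)])
  }
  expect_error(to_ras(volume(array(0, c(3, 3, 3)), orientation = "RAR")),
               "orientation")
})

test_that("rescale_intensity clips at the histogram 99.9% ceiling", {
  # linear ramp: ceiling ~ the 99.9th percentile, maximum output 255
  n <- 1e6
  ramp <- volume(array(seq(0, 1000, length.out = n), c(100, 100, 100)))
  r <- rescale_intensity(ramp)
  expect_equal(max(r$data), 255)
  srt <- sort(as.numeric(ramp$data))
  p999 <- srt[ceiling(0.999 * n)]
  ceiling_est <- min(ramp$data[r$data == 255])
  expect_lt(abs(ceiling_est - p999), 2)  # one 1-mm bin of the 1000-bin histogram
  # a single extreme outlier must not collapse the bulk dynamic range
  set.seed(9)
  x <- array(runif(64^3), c(64, 64, 64))
  x[1] <- 1e6
  r2 <- rescale_intensity(volume(x))
  expect_equal(r2$data[1], 255)
  bulk <- r2$data[-1]
  expect_gt(max(bulk) - min(bulk), 200)
  # constant volume maps to all zeros, no error
  expect_true(all(rescale_intensity(volume(array(5, c(4, 4, 4))))$data == 0))
})

test_that("rescale_intensity preserves intensity order below the ceiling", {
  set.seed(11)
  x <- array(rnorm(20^3), c(20, 20, 20))
  r <- rescale_intensity(volume(x))
  below <- r$data < 255
  ord <- order(x[below])
  expect_true(all(diff(r$data[below][ord]) >= 0))
})

test_that("conform yields a cubic isotropic RAS [0,1] volume and is idempotent", {
  v <- volume(tiny_phantom(5L, shape = c(24L, 26L, 16L),
                           voxel = c(1, 1, 1.2))$data,
              c(1.0, 1.0, 1.2), "RAS", "unit_0_1")
  cv <- conform(v)
  expect_equal(cv$iso_voxel, 1.0)
  expect_equal(cv$side, 26L)
  expect_equal(dim(cv$data), rep(26L, 3))
  # randomized anisotropic phantoms
  set.seed(21)
  for (rep in 1:3) {
    dims <- sample(18:34, 3L)
    vox <- runif(3, 0.7, 1.5)
    orient <- sample(c("RAS", "LPS", "PIR"), 1L)
    ph <- tiny_phantom(30L + rep, shape = dims, voxel = vox)
    vv <- volume(ph$data, vox, orient, "unit_0_1")
    cc <- conform(vv)
    expect_equal(dim(cc$data), rep(max(dims), 3))
    expect_equal(cc$voxel_size, rep(min(vox), 3))
    expect_identical(cc$orientation, "RAS")
    expect_gte(min(cc$data), 0)
    expect_lte(max(cc$data), 1)
    cc2 <- conform(cc)
    expect_lt(max(abs(cc2$data - cc$data)), 1e-6)
  }
  expect_error(conform(volume(array(0, c(1, 4, 4)))), "degenerate")
})
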