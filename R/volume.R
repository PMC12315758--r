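# Volume container, NIfTI/MGH input-output, and the conforming pipeline:
# resample to an isotropic cube, reorient to RAS, rescale intensities to
# 8-bit through a clipped histogram, then map linearly to [0, 1].

ORIENT_LETTERS <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
ORIENT_POS <- c("R", "A", "S")

check_orientation <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("orientation must be a 3-letter axis code such as 'RAS'")
  lets <- strsplit(code, "")[[1]]
  if (!all(lets %in% names(ORIENT_LETTERS)) ||
      anyDuplicated(ORIENT_LETTERS[lets]))
    stop("unrecognized orientation code: ", code)
  lets
}

#' Construct a 3D volume
#'
#' The universal currency of the pipeline: a 3D intensity grid with voxel
#' sizes in millimetres, an axis-orientation code (direction of increasing
#' index along each array axis, e.g. "RAS"), and an intensity scale.
#'
#' @param data numeric 3D array.
#' @param voxel_size positive length-3 numeric (mm).
#' @param orientation 3-letter code, one letter per array axis.
#' @param intensity_scale one of "raw", "uint8_0_255", "unit_0_1".
#' @export
volume <- function(data, voxel_size = c(1, 1, 1), orientation = "RAS",
                   intensity_scale = c("raw", "uint8_0_255", "unit_0_1")) {
  intensity_scale <- match.arg(intensity_scale)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("volume data contains non-finite values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values")
  check_orientation(orientation)
  if (intensity_scale == "unit_0_1" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("unit_0_1 volumes must have intensities in [0, 1]")
  structure(list(data = data, voxel_size = voxel_size,
                 orientation = orientation,
                 intensity_scale = intensity_scale),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s, voxel %s mm, %s, %s, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$orientation, x$intensity_scale, min(x$data), max(x$data)))
  invisible(x)
}

is_conformed <- function(vol) {
  inherits(vol, "conformed_volume") ||
    (length(unique(dim(vol$data))) == 1L &&
       length(unique(vol$voxel_size)) == 1L &&
       identical(vol$orientation, "RAS") &&
       identical(vol$intensity_scale, "unit_0_1"))
}

# ---- reading and writing --------------------------------------------------

#' Read a NIfTI or MGH volume
#'
#' Voxel sizes and orientation are taken from the header; the orientation
#' code reports the direction of increasing index along each array axis
#' (the reader never reorients). Data are cast to double.
#' @param path file ending in .nii, .nii.gz, .mgh or .mgz.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("failed to read NIfTI file ",
                                             path, ": ", conditionMessage(e)))
    dat <- as.array(img)
    if (length(dim(dat)) == 4L && dim(dat)[4] == 1L) dim(dat) <- dim(dat)[1:3]
    if (length(dim(dat)) != 3L) stop("expected a 3D volume in ", path)
    vx <- abs(RNifti::pixdim(img))[1:3]
    orient <- RNifti::orientation(img)
  } else if (grepl("\\.(mgh|mgz)$", lp)) {
    m <- read_mgh(path)
    dat <- m$data; vx <- m$voxel_size; orient <- m$orientation
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .mgh or .mgz)")
  }
  dat <- array(as.numeric(dat), dim(dat))  # strip reader attributes
  dat[!is.finite(dat)] <- 0
  volume(dat, voxel_size = vx, orientation = orient, intensity_scale = "raw")
}

#' Write a volume to NIfTI or MGH
#'
#' The header records the voxel sizes and an axis-aligned affine encoding
#' the volume's orientation code.
#' @param vol an [volume()].
#' @param path output path; format chosen by extension.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: no such directory: ", dirname(path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$voxel_size
    aff <- orientation_affine(vol$orientation, vol$voxel_size, dim(vol$data))
    RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mgh|mgz)$", lp)) {
    write_mgh(vol, path)
  } else {
    stop("unsupported output format: ", path,
         " (expected .nii, .nii.gz, .mgh or .mgz)")
  }
  invisible(path)
}

orientation_dircols <- function(code) {
  lets <- check_orientation(code)
  m <- matrix(0, 3, 3)
  for (k in 1:3) {
    ax <- ORIENT_LETTERS[[lets[k]]]
    m[ax, k] <- if (lets[k] %in% ORIENT_POS) 1 else -1
  }
  m
}

orientation_affine <- function(code, voxel_size, dims) {
  m <- orientation_dircols(code)
  aff <- diag(4)
  aff[1:3, 1:3] <- m %*% diag(voxel_size)
  # place the volume centre at the world origin
  aff[1:3, 4] <- -aff[1:3, 1:3] %*% ((dims - 1) / 2)
  aff
}

# ---- MGH format (FreeSurfer), big-endian ----------------------------------

read_mgh <- function(path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rd <- function(what, n, size) {
    x <- readBin(con, what, n = n, size = size, endian = "big")
    if (length(x) != n) stop("truncated MGH file: ", path)
    x
  }
  v <- rd(integer(), 1L, 4L)
  if (v != 1L) stop("not an MGH file (bad version field): ", path)
  dims <- rd(integer(), 4L, 4L)
  type <- rd(integer(), 1L, 4L)
  rd(integer(), 1L, 4L)                      # dof, unused
  good_ras <- rd(integer(), 1L, 2L)
  if (good_ras == 1L) {
    delta <- rd(numeric(), 3L, 4L)
    mdc <- matrix(rd(numeric(), 9L, 4L), 3, 3)
    rd(numeric(), 3L, 4L)                    # Pxyz_c, unused
    used <- 4L + 16L + 4L + 4L + 2L + 12L + 36L + 12L
  } else {
    delta <- c(1, 1, 1)
    mdc <- diag(3)
    used <- 4L + 16L + 4L + 4L + 2L
  }
  readBin(con, raw(), n = 284L - used)       # pad to the 284-byte header
  n <- prod(dims[1:3]) * max(1L, dims[4])
  dat <- switch(as.character(type),
                "0" = as.numeric(rd(integer(), n, 1L)),
                "1" = as.numeric(rd(integer(), n, 4L)),
                "3" = rd(numeric(), n, 4L),
                "4" = as.numeric(rd(integer(), n, 2L)),
                stop("unsupported MGH data type: ", type))
  dat <- array(dat[seq_len(prod(dims[1:3]))], dims[1:3])
  orient <- paste(vapply(1:3, function(k) {
    ax <- which.max(abs(mdc[, k]))
    if (mdc[ax, k] >= 0) ORIENT_POS[ax] else c("L", "P", "I")[ax]
  }, ""), collapse = "")
  check_orientation(orient)
  list(data = dat, voxel_size = abs(delta), orientation = orient)
}

write_mgh <- function(vol, path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(x, con, size = size, endian = "big")
  d <- dim(vol$data)
  wr(1L, 4L)
  wr(as.integer(c(d, 1L)), 4L)
  wr(3L, 4L)                                  # float data
  wr(0L, 4L)                                  # dof
  wr(1L, 2L)                                  # goodRASFlag
  wr(as.numeric(vol$voxel_size), 4L)
  wr(as.numeric(orientation_dircols(vol$orientation)), 4L)
  wr(c(0, 0, 0), 4L)                          # Pxyz_c
  used <- 4L + 16L + 4L + 4L + 2L + 12L + 36L + 12L
  writeBin(raw(284L - used), con)
  wr(as.numeric(vol$data), 4L)
  invisible(path)
}

# ---- conforming -----------------------------------------------------------

#' Reorient a volume to RAS
#'
#' Permutes and flips the array axes so that indices increase towards the
#' Right, Anterior and Superior directions; voxel sizes are permuted
#' consistently and intensities are untouched.
#' @param vol an [volume()].
#' @export
to_ras <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  lets <- check_orientation(vol$orientation)
  axes <- ORIENT_LETTERS[lets]
  perm <- match(1:3, axes)
  dat <- aperm(vol$data, perm)
  vx <- vol$voxel_size[perm]
  for (t in 1:3) {
    if (!(lets[perm[t]] %in% ORIENT_POS)) {
      idx <- rev(seq_len(dim(dat)[t]))
      dat <- switch(t, dat[idx, , , drop = FALSE], dat[, idx, , drop = FALSE],
                    dat[, , idx, drop = FALSE])
    }
  }
  volume(dat, voxel_size = vx, orientation = "RAS",
         intensity_scale = vol$intensity_scale)
}

#' Histogram-based 8-bit intensity rescaling
#'
#' Builds a 1000-bin histogram of the intensities and clips at the smallest
#' bin edge above which at most one thousandth of the voxels lie, so that a
#' handful of extreme outliers cannot compress the dynamic range. When the
#' ceiling collapses the range substantially (an extreme-outlier regime in
#' which the whole bulk falls into a few bins), the histogram is rebuilt on
#' the clipped range until the ceiling is stable at bin granularity. The
#' minimum maps to 0 and the clipping ceiling to 255; outputs are rounded
#' to integers. A constant-valued volume maps to all zeros.
#' @param vol an [volume()] with finite values.
#' @export
rescale_intensity <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  x <- vol$data
  mn <- min(x); mx <- max(x)
  if (mx - mn <= 0) {
    return(volume(array(0, dim(x)), vol$voxel_size, vol$orientation,
                  "uint8_0_255"))
  }
  srt <- sort(as.numeric(x))
  n <- length(srt)
  for (pass in 1:10) {
    edges <- seq(mn, mx, length.out = 1001L)
    n_above <- n - findInterval(edges, srt)
    k <- which(n_above <= n / 1000)[1]
    ceiling_val <- if (k <= 1L || edges[k] <= mn) mx else edges[k]
    if (ceiling_val - mn > 0.5 * (mx - mn)) break
    mx <- ceiling_val
  }
  y <- pmin(x, ceiling_val)
  y <- round((y - mn) / (ceiling_val - mn) * 255)
  volume(array(y, dim(x)), vol$voxel_size, vol$orientation, "uint8_0_255")
}

#' Conform a volume to a cubic, isotropic, RAS, [0, 1] grid
#'
#' Reorients to RAS, resamples every axis to `max(dim)` samples by linear
#' interpolation (half-pixel-centre convention, no corner alignment),
#' applies the clipped-histogram 8-bit rescaling, and maps linearly to
#' [0, 1]. The recorded isotropic voxel size is `min(voxel_size)` mm.
#'
#' @param vol an [volume()].
#' @param internal_interp interpolation mode; only "linear" is provided.
#' @return a `conformed_volume` (subclass of `mri_volume`) with fields
#'   `side` and `iso_voxel`.
#' @export
conform <- function(vol, internal_interp = "linear") {
  stopifnot(inherits(vol, "mri_volume"))
  if (!identical(internal_interp, "linear"))
    stop("only linear interpolation is supported")
  if (any(dim(vol$data) < 2L)) stop("degenerate volume: every dimension must be >= 2")
  v <- to_ras(vol)
  side <- max(dim(v$data))
  iso <- min(v$voxel_size)
  dat <- cpp_resize_trilinear(v$data, side, side, side)
  # Fixed point: a volume already on the conformed grid (cubic, isotropic,
  # RAS, intensities on the 8-bit [0, 1] lattice) passes through unchanged;
  # re-running the histogram clip would serve no purpose on its own output.
  on_grid <- vol$intensity_scale == "unit_0_1" &&
    max(abs(dat * 255 - round(dat * 255))) < 1e-9
  if (on_grid) {
    out <- volume(dat, rep(iso, 3), "RAS", "unit_0_1")
  } else {
    r <- rescale_intensity(volume(dat, rep(iso, 3), "RAS", "raw"))
    out <- volume(r$data / 255, rep(iso, 3), "RAS", "unit_0_1")
  }
  out$side <- side
  out$iso_voxel <- iso
  class(out) <- c("conformed_volume", class(out))
  out
}
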