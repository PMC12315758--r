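# Full-volume inference: slab extraction per anatomical plane, per-slice
# denoising, three-plane view aggregation, and reassembly in conformed
# space.  In RAS voxel space the plane normals are: sagittal = axis 1 (R),
# coronal = axis 2 (A), axial = axis 3 (S).

plane_axis <- function(plane) {
  switch(match.arg(plane, c("axial", "coronal", "sagittal")),
         axial = 3L, coronal = 2L, sagittal = 1L)
}

slice_along <- function(data, axis, k) {
  switch(axis, data[k, , ], data[, k, ], data[, , k])
}

#' Extract the 7-slice slabs of one anatomical plane
#'
#' For every slice index k along the plane's normal axis the slab channels
#' are slices k-3..k+3, with edge replication beyond the boundary; the
#' middle channel is slice k itself.
#'
#' @param vol a conformed volume.
#' @param plane "axial", "coronal" or "sagittal".
#' @param channels slab thickness (odd, default 7).
#' @return a `plane_stack`: list with `plane`, `slabs`
#'   (array `n x C x H x W`) and `native_res`.
#' @export
extract_slabs <- function(vol, plane = "axial", channels = 7L) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!is_conformed(vol)) stop("extract_slabs expects a conformed volume")
  axis <- plane_axis(plane)
  S <- dim(vol$data)[axis]
  if (S < channels) stop("volume side must be at least ", channels)
  half <- channels %/% 2L
  hw <- dim(vol$data)[-axis]
  slabs <- array(0, c(S, channels, hw[1], hw[2]))
  for (k in seq_len(S)) {
    ks <- pmin(pmax(k + (-half):half, 1L), S)
    for (c in seq_len(channels))
      slabs[k, c, , ] <- slice_along(vol$data, axis, ks[c])
  }
  structure(list(plane = plane, slabs = slabs,
                 native_res = min(vol$voxel_size)),
            class = "plane_stack")
}

#' Denoise a conformed volume along one anatomical plane
#'
#' Runs [denoise_slab()] over every slab of the plane and reassembles the
#' denoised slices in order.
#' @param network an `mri_denoiser`.
#' @param vol a conformed volume.
#' @param plane "axial", "coronal" or "sagittal".
#' @param batch_size slabs per forward batch.
#' @export
denoise_plane <- function(network, vol, plane = "axial", batch_size = 8L) {
  ps <- extract_slabs(vol, plane, network$config$input_channels)
  axis <- plane_axis(plane)
  S <- dim(ps$slabs)[1]
  out <- vol$data
  for (start in seq(1L, S, by = batch_size)) {
    ks <- start:min(start + batch_size - 1L, S)
    sb <- slab_batch(ps$slabs[ks, , , , drop = FALSE], plane, ps$native_res)
    den <- denoise_slab(network, sb)
    for (i in seq_along(ks)) {
      k <- ks[i]
      if (axis == 1L) out[k, , ] <- den[i, , ]
      else if (axis == 2L) out[, k, ] <- den[i, , ]
      else out[, , k] <- den[i, , ]
    }
  }
  res <- volume(out, vol$voxel_size, vol$orientation, "raw")
  res$side <- vol$side; res$iso_voxel <- vol$iso_voxel
  class(res) <- class(vol)
  res$intensity_scale <- "raw"
  res
}

#' Average the three per-plane denoised volumes
#'
#' Voxelwise mean with equal weights 1/3; symmetric in its arguments.
#' @param vol_ax,vol_cor,vol_sag volumes of identical shape.
#' @export
view_aggregate <- function(vol_ax, vol_cor, vol_sag) {
  vols <- list(vol_ax, vol_cor, vol_sag)
  dats <- lapply(vols, function(v) if (inherits(v, "mri_volume")) v$data else as.array(v))
  if (!all(vapply(dats, function(d) identical(dim(d), dim(dats[[1]])), TRUE)))
    stop("view_aggregate: shape mismatch")
  avg <- (dats[[1]] + dats[[2]] + dats[[3]]) / 3
  if (inherits(vol_ax, "mri_volume")) {
    out <- vol_ax
    out$data <- avg
    out
  } else avg
}

#' Denoise a full volume with three-plane view aggregation
#'
#' Conforms the input, denoises it once per anatomical plane with the same
#' network weights, averages the three results, and clamps to [0, 1].
#' The output stays in conformed space by default.
#'
#' @param network an `mri_denoiser`.
#' @param vol any readable volume.
#' @param clamp clamp output intensities into [0, 1] (default TRUE).
#' @param native_grid resample the result back to the input's grid shape
#'   (off by default; evaluation happens in conformed space).
#' @param verbose log per-plane timing.
#' @export
denoise_volume <- function(network, vol, clamp = TRUE, native_grid = FALSE,
                           verbose = FALSE) {
  cv <- if (is_conformed(vol)) vol else conform(vol)
  outs <- lapply(c("axial", "coronal", "sagittal"), function(pl) {
    t0 <- Sys.time()
    r <- denoise_plane(network, cv, pl)
    if (verbose)
      message(sprintf("[%s] plane %s denoised in %.1fs",
                      format(Sys.time(), "%H:%M:%S"), pl,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  })
  agg <- view_aggregate(outs[[1]], outs[[2]], outs[[3]])
  dat <- if (clamp) pmin(pmax(agg$data, 0), 1) else agg$data
  out <- volume(array(dat, dim(dat)), cv$voxel_size, "RAS",
                if (clamp) "unit_0_1" else "raw")
  out$side <- cv$side; out$iso_voxel <- cv$iso_voxel
  class(out) <- c("conformed_volume", class(out))
  if (native_grid && !is_conformed(vol)) {
    nd <- dim(vol$data)
    out <- volume(pmin(pmax(cpp_resize_trilinear(out$data, nd[1], nd[2], nd[3]), 0), 1),
                  vol$voxel_size, "RAS", "unit_0_1")
  }
  out
}
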