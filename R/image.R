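#' Ortho-positronium lifetime image
#'
#' Container for voxel-wise fit results: the tau3 posterior-mean map, its
#' posterior SD and relative SD, the BR3 map, the QC mask and a
#' convergence mask, all on one [voxel_grid()]. Masked voxels carry `NA`
#' (distinct from any physical lifetime). No smoothing or filtering is
#' ever applied to the maps.
#'
#' @param grid a [voxel_grid()].
#' @param tau3_map,tau3_sd_map,br3_map numeric arrays of dim `grid$dims`.
#' @param qc_mask logical array: background QC result.
#' @param conv_mask logical array: sampler convergence (NA where not
#'   fitted).
#' @param fits tibble of per-voxel summaries.
#' @param provenance list of reproducibility metadata (seed, sampler
#'   configuration, stage counts).
#' @return An object of class `lifetime_image`.
#' @export
lifetime_image <- function(grid, tau3_map, tau3_sd_map, br3_map,
                           qc_mask, conv_mask, fits = NULL,
                           provenance = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  for (a in list(tau3_map, tau3_sd_map, br3_map, qc_mask, conv_mask)) {
    if (!identical(dim(a), as.integer(grid$dims))) {
      stop("all maps must share the grid dimensions")
    }
  }
  relsd <- tau3_sd_map / tau3_map
  structure(
    list(grid = grid, tau3_map = tau3_map, tau3_sd_map = tau3_sd_map,
         tau3_relsd_map = relsd, br3_map = br3_map, qc_mask = qc_mask,
         conv_mask = conv_mask, fits = fits, provenance = provenance),
    class = "lifetime_image"
  )
}

#' @export
print.lifetime_image <- function(x, ...) {
  d <- x$grid$dims
  cat(sprintf("<lifetime_image> %d x %d x %d voxels of %.1f x %.1f x %.1f mm\n",
              d[1], d[2], d[3], x$grid$voxel_size[1], x$grid$voxel_size[2],
              x$grid$voxel_size[3]))
  nf <- sum(!is.na(x$tau3_map))
  cat(sprintf("  %d voxels mapped; tau3 range %.2f-%.2f ns\n", nf,
              suppressWarnings(min(x$tau3_map, na.rm = TRUE)),
              suppressWarnings(max(x$tau3_map, na.rm = TRUE))))
  invisible(x)
}

#' Write / read a lifetime image as NIfTI volumes
#'
#' Writes `<prefix>_tau3.nii`, `<prefix>_tau3_sd.nii`, `<prefix>_br3.nii`
#' and `<prefix>_qc.nii` (double precision; masked voxels stored as NaN)
#' with the voxel size on the affine diagonal, plus a JSON sidecar
#' `<prefix>.json` carrying grid metadata and provenance. The round trip
#' is bit-exact for maps and metadata.
#'
#' @param image a `lifetime_image`.
#' @param prefix output path prefix.
#' @return `read_image()` returns the `lifetime_image`.
#' @export
write_image <- function(image, prefix) {
  stopifnot(inherits(image, "lifetime_image"))
  vs <- image$grid$voxel_size
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vs
    RNifti::writeNifti(img, paste0(prefix, "_", suffix, ".nii"),
                       datatype = "double")
  }
  wr(image$tau3_map, "tau3")
  wr(image$tau3_sd_map, "tau3_sd")
  wr(image$br3_map, "br3")
  wr(array(as.numeric(image$qc_mask), image$grid$dims), "qc")
  conv <- array(as.numeric(image$conv_mask), image$grid$dims)
  wr(conv, "conv")
  meta <- list(origin = image$grid$origin, voxel_size = vs,
               dims = image$grid$dims, provenance = image$provenance)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_image
#' @param prefix path prefix used by [write_image()].
#' @export
read_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  grid <- voxel_grid(meta$origin, meta$voxel_size, meta$dims)
  rd <- function(suffix) {
    img <- RNifti::readNifti(paste0(prefix, "_", suffix, ".nii"))
    if (!identical(dim(img), as.integer(grid$dims))) {
      stop("image dimensions do not match the sidecar metadata")
    }
    pd <- RNifti::pixdim(img)
    if (any(abs(pd - grid$voxel_size) > 1e-5)) {
      stop("NIfTI voxel size does not match the sidecar metadata")
    }
    array(as.numeric(img), grid$dims)
  }
  conv_num <- rd("conv")
  lifetime_image(grid, rd("tau3"), rd("tau3_sd"), rd("br3"),
                 array(rd("qc") > 0.5, grid$dims),
                 array(ifelse(is.na(conv_num), NA, conv_num > 0.5),
                       grid$dims),
                 provenance = meta$provenance)
}

#' Maximum intensity projection
#'
#' Per-ray maximum over unmasked (non-`NA`) voxels along the chosen axis;
#' rays with no unmasked voxel give a masked (`NA`) output pixel.
#'
#' @param map 3D numeric array (or a `lifetime_image`, whose
#'   `tau3_relsd_map` is projected by default via `which`).
#' @param axis projection axis: `"x"`, `"y"` or `"z"`.
#' @return 2D array of per-ray maxima.
#' @export
mip <- function(map, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  if (inherits(map, "lifetime_image")) map <- map$tau3_relsd_map
  stopifnot(length(dim(map)) == 3L)
  margin <- switch(axis, x = c(2L, 3L), y = c(1L, 3L), z = c(1L, 2L))
  apply(map, margin, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  })
}

#' Extract a 2D slice from a lifetime image
#'
#' `plane = "zy"` returns the (z, y) plane at a fixed x index (the view
#' used for separated tubes); `plane = "xy"` returns the (x, y) plane at a
#' fixed z index (top view).
#'
#' @param image a `lifetime_image` or 3D array.
#' @param plane `"zy"` or `"xy"`.
#' @param index 1-based slice index along the remaining axis.
#' @param what which map to slice for a `lifetime_image`; default
#'   `"tau3_map"`.
#' @return 2D array: dims `(nz, ny)` for `"zy"`, `(nx, ny)` for `"xy"`.
#' @export
slice_view <- function(image, plane = c("zy", "xy"), index, what = "tau3_map") {
  plane <- match.arg(plane)
  arr <- if (inherits(image, "lifetime_image")) image[[what]] else image
  d <- dim(arr)
  if (plane == "zy") {
    if (index < 1 || index > d[1]) stop("slice index out of range")
    t(arr[index, , ])            # (nz, ny)
  } else {
    if (index < 1 || index > d[3]) stop("slice index out of range")
    arr[, , index]               # (nx, ny)
  }
}
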