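#' Axis-aligned voxel grid
#'
#' Voxel `(i, j, k)` (1-based) spans the half-open box
#' `[origin + (i-1)*size, origin + i*size)` along each axis.
#'
#' @param origin length-3 lower corner (mm).
#' @param voxel_size scalar or length-3 voxel edge lengths (mm).
#' @param dims length-3 integer voxel counts.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, voxel_size, dims) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(origin) == 3L, length(voxel_size) == 3L,
            length(dims) == 3L)
  if (any(voxel_size <= 0) || any(dims < 1)) stop("degenerate voxel grid")
  structure(list(origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size),
                 dims = as.integer(dims)),
            class = "voxel_grid")
}

#' Grid covering a phantom
#'
#' Builds a cubic-voxel grid whose extent covers the phantom bounding box
#' plus a margin, centred on the bounding-box centre.
#'
#' @param phantom list of [tube_region()].
#' @param voxel_size cubic voxel edge (mm), e.g. 10.0, 7.1 or 4.0.
#' @param margin extra extent on each side (mm); allow for TOF blur.
#' @return A [voxel_grid()].
#' @export
grid_for_phantom <- function(phantom, voxel_size, margin = 20) {
  bb <- phantom_bbox(phantom)
  ctr <- colMeans(bb)
  dims <- pmax(1L, as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * margin) /
                                        voxel_size)))
  voxel_grid(ctr - dims * voxel_size / 2, voxel_size, dims)
}

#' Assign three-photon events to voxels
#'
#' Each event vertex is assigned by the half-open floor rule; vertices
#' outside the grid are dropped and counted.
#'
#' @param events tibble with `vx`, `vy`, `vz`, `delta_t`.
#' @param grid a [voxel_grid()].
#' @return Tibble with one row per occupied voxel: integer indices `ix`,
#'   `iy`, `iz` (1-based), event count `n`, and list-column `deltas` of the
#'   voxel's time differences. Attribute `"n_dropped"` counts out-of-grid
#'   events.
#' @export
bin_vertices <- function(events, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ix <- floor((events$vx - grid$origin[1]) / grid$voxel_size[1])
  iy <- floor((events$vy - grid$origin[2]) / grid$voxel_size[2])
  iz <- floor((events$vz - grid$origin[3]) / grid$voxel_size[3])
  inside <- ix >= 0 & ix < grid$dims[1] & iy >= 0 & iy < grid$dims[2] &
    iz >= 0 & iz < grid$dims[3]
  out <- tibble::tibble(ix = as.integer(ix[inside]) + 1L,
                        iy = as.integer(iy[inside]) + 1L,
                        iz = as.integer(iz[inside]) + 1L,
                        delta_t = events$delta_t[inside]) |>
    dplyr::group_by(.data$ix, .data$iy, .data$iz) |>
    dplyr::summarise(n = dplyr::n(), deltas = list(.data$delta_t),
                     .groups = "drop")
  structure(out, n_dropped = sum(!inside))
}

#' Build a time-difference distribution histogram
#'
#' Uniform half-open bins of width `bin_width` starting at `range[1]`;
#' the number of bins is `floor(diff(range) / bin_width)`, so with the
#' 133 ps default the histogram covers `[-5, 7.901)` ns. Values outside
#' the binned support are dropped and counted.
#'
#' @param deltas numeric vector of time differences (ns).
#' @param bin_width bin width (ns); default 0.133.
#' @param range length-2 histogram extent (ns); the default lower edge
#'   `-5` ns leaves ~19 bins below the `-2.5` ns background cutoff.
#' @return An object of class `tdd`: bin edges, centers, integer counts,
#'   and (once [estimate_background()] has run) the fixed background level
#'   `b`, its relative error, and the QC flag.
#' @export
build_tdd <- function(deltas, bin_width = 0.133, range = c(-5, 8)) {
  stopifnot(bin_width > 0, range[1] < range[2])
  n_bins <- floor((range[2] - range[1]) / bin_width + 1e-9)
  edges <- range[1] + (0:n_bins) * bin_width
  idx <- floor((deltas - range[1]) / bin_width)
  inside <- idx >= 0 & idx < n_bins
  counts <- tabulate(idx[inside] + 1L, nbins = n_bins)
  structure(
    list(edges = edges, centers = edges[-1] - bin_width / 2,
         counts = counts, bin_width = bin_width,
         n_dropped = sum(!inside), n = sum(counts),
         b = NA_real_, b_rel_err = NA_real_, qc_pass = NA),
    class = "tdd"
  )
}

#' @export
print.tdd <- function(x, ...) {
  cat("<tdd> ", length(x$counts), " bins of ", x$bin_width * 1e3,
      " ps over [", x$edges[1], ", ", x$edges[length(x$edges)],
      ") ns, ", x$n, " events", sep = "")
  if (!is.na(x$b)) {
    cat(sprintf("; background b = %.3g/bin (rel err %.1f%%, QC %s)",
                x$b, 100 * x$b_rel_err, ifelse(isTRUE(x$qc_pass), "pass", "fail")))
  }
  cat("\n")
  invisible(x)
}

#' Fix the flat background of a TDD
#'
#' The background level `b` is the mean bin content over bins whose
#' centers lie below `cutoff`; its relative error is the standard error of
#' that mean divided by `b`. A voxel passes QC when the relative error is
#' strictly below `qc_threshold`; `b = 0` gives an infinite relative error
#' and fails QC.
#'
#' @param tdd a [build_tdd()] histogram with at least 2 bins below the
#'   cutoff.
#' @param cutoff background region upper limit (ns); default -2.5.
#' @param qc_threshold QC limit on the relative error; default 0.20.
#' @return The `tdd` with `b`, `b_rel_err` and `qc_pass` set.
#' @export
estimate_background <- function(tdd, cutoff = -2.5, qc_threshold = 0.2) {
  stopifnot(inherits(tdd, "tdd"))
  bg <- tdd$counts[tdd$centers < cutoff]
  if (length(bg) < 2L) stop("need at least 2 bins below the background cutoff")
  b <- mean(bg)
  rel <- if (b > 0) (stats::sd(bg) / sqrt(length(bg))) / b else Inf
  tdd$b <- b
  tdd$b_rel_err <- rel
  tdd$qc_pass <- is.finite(rel) && rel < qc_threshold
  tdd
}

#' Per-voxel TDDs with background and QC
#'
#' Bins events into voxels, builds each voxel's TDD, fixes its background
#' and evaluates the QC filter in one pass.
#'
#' @inheritParams bin_vertices
#' @inheritParams build_tdd
#' @inheritParams estimate_background
#' @return Tibble with `ix`, `iy`, `iz`, `n`, list-column `tdd`, and the
#'   unnested `b`, `b_rel_err`, `qc_pass` columns. Attribute `"n_dropped"`
#'   carries the out-of-grid count.
#' @export
voxel_tdds <- function(events, grid, bin_width = 0.133, range = c(-5, 8),
                       cutoff = -2.5, qc_threshold = 0.2) {
  binned <- bin_vertices(events, grid)
  out <- binned |>
    dplyr::mutate(tdd = purrr::map(.data$deltas, function(d) {
      estimate_background(build_tdd(d, bin_width, range), cutoff, qc_threshold)
    })) |>
    dplyr::mutate(b = purrr::map_dbl(.data$tdd, "b"),
                  b_rel_err = purrr::map_dbl(.data$tdd, "b_rel_err"),
                  qc_pass = purrr::map_lgl(.data$tdd, "qc_pass")) |>
    dplyr::select(-"deltas")
  structure(out, n_dropped = attr(binned, "n_dropped"))
}

#' Apply the background-error QC filter to a voxel table
#'
#' Keeps the table intact and (re)computes the `qc_pass` mask: a voxel
#' passes when its background relative error is strictly below the
#' threshold.
#'
#' @param voxels tibble from [voxel_tdds()].
#' @param qc_threshold relative-error limit; default 0.20.
#' @return The tibble with an updated `qc_pass` column; attribute
#'   `"qc_counts"` holds the pass/fail totals.
#' @export
qc_filter <- function(voxels, qc_threshold = 0.2) {
  voxels$qc_pass <- is.finite(voxels$b_rel_err) &
    voxels$b_rel_err < qc_threshold
  structure(voxels, qc_counts = c(pass = sum(voxels$qc_pass),
                                  fail = sum(!voxels$qc_pass)))
}

#' Aggregate a region's events into one TDD
#'
#' @param events three-photon event tibble.
#' @param bin_width,range,cutoff,qc_threshold as in [build_tdd()] and
#'   [estimate_background()].
#' @return A `tdd` with background fixed.
#' @export
region_tdd <- function(events, bin_width = 0.133, range = c(-5, 8),
                       cutoff = -2.5, qc_threshold = 0.2) {
  estimate_background(build_tdd(events$delta_t, bin_width, range),
                      cutoff, qc_threshold)
}
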