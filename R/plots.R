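#' Plot a TDD with an optional fitted model
#'
#' @param object a `tdd`.
#' @param fit optional `pslife_fit` whose posterior-mean expectation is
#'   overlaid on the fit range.
#' @param log_y plot counts on a log scale (the usual view of a lifetime
#'   spectrum); default `TRUE`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tdd <- function(object, fit = NULL, log_y = TRUE, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_step(direction = "mid", colour = "grey30") +
    ggplot2::labs(x = "time difference (ns)", y = "counts per bin")
  if (!is.na(object$b)) {
    p <- p + ggplot2::geom_hline(yintercept = object$b,
                                 linetype = "dashed", colour = "grey60")
  }
  if (!is.null(fit)) {
    s <- fit$summary
    params <- lifetime_params(tau3 = s$tau3_mean, br = s$br_mean,
                              sigma = s$sigma_mean, delta = s$delta_mean,
                              n_total = s$n_mean, b = fit$data$b)
    mdl <- tibble::tibble(
      center = fit$data$centers,
      mu = model_mu(fit$data$centers, fit$data$bin_width, params)
    )
    p <- p + ggplot2::geom_line(data = mdl,
                                ggplot2::aes(y = .data$mu),
                                colour = "firebrick", linewidth = 0.7)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot posterior draws of a fit
#'
#' Marginal posterior histograms of the sampled parameters.
#'
#' @param object a `pslife_fit`.
#' @param pars parameters to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pslife_fit <- function(object,
                                pars = c("tau3", "br1", "br2", "br3",
                                         "sigma", "delta"), ...) {
  df <- object$draws |>
    dplyr::select(dplyr::all_of(pars)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior draws")
}

#' Plot a slice of a lifetime image
#'
#' @param object a `lifetime_image`.
#' @param plane,index as in [slice_view()].
#' @param what map to display; default `"tau3_map"`.
#' @param ... unused.
#' @return A ggplot object (masked voxels blank).
#' @export
autoplot.lifetime_image <- function(object, plane = "xy",
                                    index = ceiling(object$grid$dims[3] / 2),
                                    what = "tau3_map", ...) {
  sl <- slice_view(object, plane, index, what)
  df <- expand.grid(row = seq_len(nrow(sl)), col = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  labs <- if (plane == "zy") c("z voxel", "y voxel") else c("x voxel", "y voxel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = if (what == "tau3_map")
                                    "tau3 (ns)" else what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[1], y = labs[2])
}

#' Plot a maximum intensity projection
#'
#' @param image a `lifetime_image` or 3D array.
#' @param axis projection axis.
#' @param what map to project for a `lifetime_image`; default the relative
#'   tau3 uncertainty map.
#' @return A ggplot object.
#' @export
plot_mip <- function(image, axis = "z", what = "tau3_relsd_map") {
  arr <- if (inherits(image, "lifetime_image")) image[[what]] else image
  m <- mip(arr, axis)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste("MIP along", axis), y = NULL)
}
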