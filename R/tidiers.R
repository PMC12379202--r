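#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a posterior fit
#'
#' One row per model parameter with posterior mean, SD and 68% HDI.
#'
#' @param x a `pslife_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (68% HDI).
#' @export
tidy.pslife_fit <- function(x, ...) {
  pars <- c("tau3", "br1", "br2", "br3", "sigma", "delta", "n_total")
  purrr::map_dfr(pars, function(p) {
    d <- x$draws[[p]]
    h <- hdi(d, 0.68)
    tibble::tibble(term = p, estimate = mean(d), std.error = stats::sd(d),
                   conf.low = h[1], conf.high = h[2])
  })
}

#' Fit-level diagnostics
#'
#' @param x a `pslife_fit`.
#' @param ... unused.
#' @return One-row tibble: net counts `A`, fixed background `b`, number of
#'   fitted bins, `rhat_max`, `ess_min`, `n_divergent`, `converged`.
#' @export
glance.pslife_fit <- function(x, ...) {
  tibble::tibble(
    A = x$data$A, b = x$data$b, n_bins = length(x$data$y),
    rhat_max = x$diagnostics$rhat_max, ess_min = x$diagnostics$ess_min,
    n_divergent = x$diagnostics$n_divergent, converged = x$converged
  )
}

#' Tidy a TDD histogram
#'
#' @param x a `tdd`.
#' @param ... unused.
#' @return Tibble with `t_lo`, `t_hi`, `center`, `count`.
#' @export
tidy.tdd <- function(x, ...) {
  tibble::tibble(t_lo = x$edges[-length(x$edges)], t_hi = x$edges[-1],
                 center = x$centers, count = x$counts)
}

#' Tidy a lifetime image
#'
#' @param x a `lifetime_image`.
#' @param ... unused.
#' @return Tibble with voxel indices, centre coordinates (mm), and the
#'   per-voxel `tau3`, `tau3_sd`, `tau3_relsd`, `br3`, `qc_pass` values.
#' @export
tidy.lifetime_image <- function(x, ...) {
  img <- x
  d <- img$grid$dims
  idx <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]),
                     iz = seq_len(d[3]))
  out <- tibble::tibble(
    ix = idx$ix, iy = idx$iy, iz = idx$iz,
    tau3 = as.vector(img$tau3_map), tau3_sd = as.vector(img$tau3_sd_map),
    tau3_relsd = as.vector(img$tau3_relsd_map),
    br3 = as.vector(img$br3_map), qc_pass = as.vector(img$qc_mask)
  )
  out$x <- img$grid$origin[1] + (out$ix - 0.5) * img$grid$voxel_size[1]
  out$y <- img$grid$origin[2] + (out$iy - 0.5) * img$grid$voxel_size[2]
  out$z <- img$grid$origin[3] + (out$iz - 0.5) * img$grid$voxel_size[3]
  out[, c("ix", "iy", "iz", "x", "y", "z", "tau3", "tau3_sd",
          "tau3_relsd", "br3", "qc_pass")]
}
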