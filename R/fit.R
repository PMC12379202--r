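#' Sampler configuration
#'
#' @param chains number of independent chains.
#' @param warmup adaptation iterations per chain (discarded).
#' @param iter kept iterations per chain.
#' @param thin keep every `thin`-th post-warmup iteration; the random-walk
#'   kernel needs modest thinning for the kept draws to be close to
#'   independent.
#' @return An object of class `sampler_control`.
#' @export
sampler_control <- function(chains = 4L, warmup = 1000L, iter = 1000L,
                            thin = 5L) {
  stopifnot(chains >= 1, warmup >= 100, iter >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin)),
            class = "sampler_control")
}

# --- unconstrained parameterization ---------------------------------------
# theta = (log tau3, alr1, alr2, log sigma, delta, nu = N / A)
# br = softmax(alr1, alr2, 0); the ALR Jacobian is prod(br).

theta_to_natural <- function(theta, A) {
  e <- exp(c(theta[2], theta[3], 0))
  br <- e / sum(e)
  list(tau3 = exp(theta[1]), br = br, sigma = exp(theta[4]),
       delta = theta[5], n_total = theta[6] * A)
}

# log posterior in theta space (priors + likelihood + transform Jacobians)
make_log_post_theta <- function(y, centers, w, b, A, prior) {
  tau1 <- TAU1_PPS; tau2 <- TAU2_DIRECT
  function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta[2:3]) > 50)) return(-Inf)
    tau3 <- exp(theta[1]); sigma <- exp(theta[4])
    if (!is.finite(tau3) || !is.finite(sigma) || tau3 <= 0 || sigma <= 0) {
      return(-Inf)
    }
    e <- exp(c(theta[2], theta[3], 0))
    br <- e / sum(e)
    delta <- theta[5]
    n_total <- theta[6] * A
    lp <- log_prior(tau3, br, sigma, delta, n_total, prior, A)
    if (!is.finite(lp)) return(-Inf)
    # Jacobians: d tau3/d theta1 = tau3, d sigma/d theta4 = sigma, ALR: prod(br)
    lp <- lp + theta[1] + theta[4] + sum(base::log(br))
    dens <- br[1] * emg_density(centers, tau1, sigma, delta) +
      br[2] * emg_density(centers, tau2, sigma, delta) +
      br[3] * emg_density(centers, tau3, sigma, delta)
    mu <- b + n_total * w * dens
    s2 <- pmax(mu, 1)
    lp - 0.5 * sum((y - mu)^2 / s2 + base::log(s2))
  }
}

# Metropolis sampler seeded at the posterior mode: a mixture kernel of
# random-walk moves (Laplace-shaped covariance, global scale adapted by
# Robbins-Monro towards 0.3 acceptance and re-estimated from the first
# warmup half) and, with probability 0.2, Metropolized independence
# proposals from a multivariate-t Laplace approximation, which
# decorrelates the chain wherever the posterior is near-Gaussian
run_chain <- function(lp, theta0, warmup, iter, L0, thin = 1L,
                      mode = theta0, p_ind = 0.2, ind_df = 4) {
  d <- length(theta0)
  n_tot <- warmup + iter * thin
  draws <- matrix(NA_real_, n_tot, d)
  theta <- theta0
  lp_cur <- lp(theta)
  if (!is.finite(lp_cur)) stop("non-finite log posterior at initial value")
  log_s <- base::log(2.38 / sqrt(d))
  L <- L0
  mode_ind <- mode
  L_ind <- 1.3 * L0
  L_ind_inv <- solve(L_ind)
  log_q_ind <- function(th) {
    z <- L_ind_inv %*% (th - mode_ind)
    -0.5 * (ind_df + d) * log1p(sum(z^2) / ind_df)
  }
  lq_cur <- log_q_ind(theta)
  w1 <- floor(warmup / 2)
  n_bad <- 0L
  for (i in seq_len(n_tot)) {
    if (stats::runif(1) < p_ind) {
      z <- stats::rnorm(d) / sqrt(stats::rchisq(1, ind_df) / ind_df)
      prop <- mode_ind + as.vector(L_ind %*% z)
      lp_prop <- lp(prop)
      lq_prop <- log_q_ind(prop)
      acc <- is.finite(lp_prop) && base::log(stats::runif(1)) <
        (lp_prop - lp_cur) - (lq_prop - lq_cur)
      rw <- FALSE
    } else {
      prop <- theta + exp(log_s) * as.vector(L %*% stats::rnorm(d))
      lp_prop <- lp(prop)
      acc <- is.finite(lp_prop) &&
        base::log(stats::runif(1)) < lp_prop - lp_cur
      rw <- TRUE
    }
    if (acc) {
      theta <- prop
      lp_cur <- lp_prop
      lq_cur <- log_q_ind(theta)
    }
    if (i > warmup && !is.finite(lp_prop)) n_bad <- n_bad + 1L
    draws[i, ] <- theta
    if (i <= warmup) {
      if (rw) log_s <- log_s + (as.numeric(acc) - 0.3) / sqrt(i)
      if (i == w1 && w1 > 4 * d) {
        half <- draws[seq_len(w1), , drop = FALSE]
        cv <- stats::cov(half) + diag(1e-10, d)
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) {
          L <- t(ch)
          log_s <- base::log(2.38 / sqrt(d))
          mode_ind <- colMeans(half)
          L_ind <- 1.3 * L
          L_ind_inv <- solve(L_ind)
          lq_cur <- log_q_ind(theta)
        }
      }
    }
  }
  kept <- draws[warmup + thin * seq_len(iter), , drop = FALSE]
  list(draws = kept, n_bad = n_bad)
}

# posterior mode and Laplace factor in theta space; the tau3 start comes
# from the log-slope of the background-subtracted tail, the rest from the
# prior means
laplace_init <- function(lp, y, centers, b, prior) {
  tail_idx <- which(centers > 2 & centers < 6.5)
  net <- pmax(y[tail_idx] - b, 0.5)
  slope <- stats::coef(stats::lm(base::log(net) ~ centers[tail_idx]))[2]
  tau3_0 <- min(max(-1 / slope, 0.5), 4)
  brm <- prior$alpha / sum(prior$alpha)
  theta0 <- c(base::log(tau3_0), base::log(brm[1] / brm[3]),
              base::log(brm[2] / brm[3]), base::log(prior$sigma_mean),
              prior$delta_mean, 1)
  opt <- tryCatch(
    stats::optim(theta0, function(th) -lp(th), method = "BFGS",
                 control = list(maxit = 500), hessian = TRUE),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value)) {
    return(list(mode = theta0, L = diag(0.05, length(theta0))))
  }
  L <- tryCatch(t(chol(solve(opt$hessian + diag(1e-8, length(theta0))))),
                error = function(e) diag(0.05, length(theta0)))
  list(mode = opt$par, L = L)
}

# split-R-hat (two halves per chain) for one parameter
split_rhat <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  halves <- cbind(mat[seq_len(h), , drop = FALSE],
                  mat[(n - h + 1L):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- h * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# effective sample size via Geyer's initial monotone positive sequence,
# summed over chains
ess_geyer <- function(mat) {
  per_chain <- apply(mat, 2, function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    rho <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                      demean = TRUE)$acf[-1]
    # sum adjacent pairs while positive and decreasing
    npair <- floor(length(rho) / 2)
    pair <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
    pos <- which(pair <= 0)
    k <- if (length(pos)) pos[1] - 1L else npair
    if (k > 1) pair[seq_len(k)] <- cummin(pair[seq_len(k)])
    tau_int <- 1 + 2 * sum(pair[seq_len(k)])
    n / max(tau_int, 1)
  })
  sum(per_chain)
}

#' Highest density interval of posterior draws
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param x numeric vector of at least 100 draws.
#' @param mass probability mass; default 0.68.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.68) {
  stopifnot(mass > 0, mass < 1)
  if (length(x) < 100L) stop("need at least 100 draws for an HDI")
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m)
  widths <- xs[starts + m] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m])
}

#' Draw from the prior distribution
#'
#' Samples the joint prior (truncated normals for `tau3` and `sigma`,
#' Dirichlet branching fractions, normal offset; the count parameter `nu`
#' is drawn on the relative scale `N / A ~ N(1, n_rel_sd)`).
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Tibble with columns `tau3`, `br1`, `br2`, `br3`, `sigma`,
#'   `delta`, `nu`.
#' @export
sample_prior <- function(prior = prior_spec(), n = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(3L * n, shape = rep(prior$alpha, each = n)),
              n, 3L)
  br <- g / rowSums(g)
  tibble::tibble(
    tau3 = rtruncnorm_pos(n, prior$tau3_mean, prior$tau3_sd),
    br1 = br[, 1], br2 = br[, 2], br3 = br[, 3],
    sigma = rtruncnorm_pos(n, prior$sigma_mean, prior$sigma_sd),
    delta = stats::rnorm(n, prior$delta_mean, prior$delta_sd),
    nu = stats::rnorm(n, 1, prior$n_rel_sd)
  )
}

# normal truncated to (0, Inf) via inverse CDF
rtruncnorm_pos <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Bayesian fit of one time-difference distribution
#'
#' Samples the posterior of `(tau3, BR, sigma, delta, N)` for a TDD whose
#' background has been fixed, using adaptive random-walk Metropolis on an
#' unconstrained transform (log lifetimes and resolution, additive
#' log-ratio for the simplex). The short lifetimes are fixed at
#' `tau1 = 125 ps` and `tau2 = 388 ps`; the background is fixed at the
#' histogram's `b`. Convergence is declared when the maximum split-R-hat
#' over parameters is below 1.01 and the minimum effective sample size
#' exceeds 400; non-convergence is reported, never silent.
#'
#' @param tdd a `tdd` with background fixed and net counts `A > 0`.
#' @param prior a [prior_spec()].
#' @param control a [sampler_control()].
#' @param seed optional integer seed (chains use consecutive substreams).
#' @param fit_range closed fit range (ns); default `c(-2, 8)`.
#' @return An object of class `pslife_fit`: posterior draws (tibble with
#'   `.chain`, `.iter` and natural-scale parameters), a summary list
#'   (means, SDs, 68% HDIs of the branching fractions), diagnostics
#'   (`rhat_max`, `ess_min`, `n_divergent`), and the fitted data.
#' @export
fit_tdd <- function(tdd, prior = prior_spec(), control = sampler_control(),
                    seed = NULL, fit_range = c(-2, 8)) {
  stopifnot(inherits(tdd, "tdd"))
  if (is.na(tdd$b)) tdd <- estimate_background(tdd)
  A <- compute_A(tdd, fit_range)
  if (!attr(A, "fittable")) stop("A <= 0: histogram is unfittable")
  A <- as.numeric(A)
  keep <- fit_bin_index(tdd, fit_range)
  lp <- make_log_post_theta(tdd$counts[keep], tdd$centers[keep],
                            tdd$bin_width, tdd$b, A, prior)
  if (!is.null(seed)) set.seed(seed)

  init <- laplace_init(lp, tdd$counts[keep], tdd$centers[keep], tdd$b, prior)
  chains <- purrr::map(seq_len(control$chains), function(ch) {
    theta0 <- init$mode + as.vector(init$L %*% stats::rnorm(length(init$mode)))
    tries <- 0L
    while (!is.finite(lp(theta0)) && tries < 50L) {
      theta0 <- init$mode +
        0.5 * as.vector(init$L %*% stats::rnorm(length(init$mode)))
      tries <- tries + 1L
    }
    if (!is.finite(lp(theta0))) theta0 <- init$mode
    run_chain(lp, theta0, control$warmup, control$iter, init$L,
              control$thin, mode = init$mode)
  })

  nat <- purrr::imap(chains, function(chain, ch) {
    th <- chain$draws
    e1 <- exp(th[, 2]); e2 <- exp(th[, 3])
    tot <- e1 + e2 + 1
    tibble::tibble(
      .chain = ch, .iter = seq_len(nrow(th)),
      tau3 = exp(th[, 1]), br1 = e1 / tot, br2 = e2 / tot, br3 = 1 / tot,
      sigma = exp(th[, 4]), delta = th[, 5], n_total = th[, 6] * A
    )
  }) |> dplyr::bind_rows()

  pars <- c("tau3", "br1", "br2", "br3", "sigma", "delta", "n_total")
  by_chain <- function(p) {
    matrix(nat[[p]], nrow = control$iter, ncol = control$chains)
  }
  rhats <- purrr::map_dbl(pars, ~ split_rhat(by_chain(.x)))
  esss <- purrr::map_dbl(pars, ~ ess_geyer(by_chain(.x)))
  diagnostics <- list(
    rhat_max = max(rhats), ess_min = min(esss),
    n_divergent = sum(purrr::map_int(chains, "n_bad"))
  )
  converged <- diagnostics$rhat_max < 1.01 && diagnostics$ess_min > 400

  summary <- list(
    tau3_mean = mean(nat$tau3), tau3_sd = stats::sd(nat$tau3),
    br_mean = c(mean(nat$br1), mean(nat$br2), mean(nat$br3)),
    br_hdi68 = list(br1 = hdi(nat$br1), br2 = hdi(nat$br2),
                    br3 = hdi(nat$br3)),
    sigma_mean = mean(nat$sigma), delta_mean = mean(nat$delta),
    n_mean = mean(nat$n_total)
  )

  structure(
    list(draws = nat, summary = summary, diagnostics = diagnostics,
         converged = converged,
         data = list(y = tdd$counts[keep], centers = tdd$centers[keep],
                     bin_width = tdd$bin_width, b = tdd$b, A = A,
                     fit_range = fit_range),
         prior = prior, control = control, seed = seed),
    class = "pslife_fit"
  )
}

#' @export
print.pslife_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pslife_fit> tau3 = %.3f +/- %.3f ns | BR3 = %.3f [%.3f, %.3f]\n",
              s$tau3_mean, s$tau3_sd, s$br_mean[3],
              s$br_hdi68$br3[1], s$br_hdi68$br3[2]))
  cat(sprintf("  sigma = %.3f ns, delta = %.3f ns, N = %.0f (A = %.0f)\n",
              s$sigma_mean, s$delta_mean, s$n_mean, x$data$A))
  cat(sprintf("  rhat_max = %.3f, ess_min = %.0f, converged: %s\n",
              x$diagnostics$rhat_max, x$diagnostics$ess_min,
              ifelse(x$converged, "yes", "NO")))
  invisible(x)
}

#' Voxel-wise Bayesian fits over a volume
#'
#' Fits every QC-passing voxel with positive net counts; failed, skipped
#' or (optionally) non-converged voxels are masked in the resulting maps.
#' Per-voxel seeds are derived deterministically from the global seed and
#' the voxel's linear index, so images are reproducible while chains stay
#' independent across voxels.
#'
#' @param voxels tibble from [voxel_tdds()].
#' @param grid the [voxel_grid()] the voxels refer to.
#' @param prior a [prior_spec()].
#' @param control a [sampler_control()]; voxel-wise fitting commonly uses
#'   a lighter configuration than whole-region fits.
#' @param seed integer seed.
#' @param fit_range closed fit range (ns).
#' @param include_nonconverged keep non-converged voxels in the maps
#'   (default `FALSE`: masked, but still listed in the fit table).
#' @return A `lifetime_image`: per-voxel maps of the tau3 posterior mean,
#'   posterior SD, relative SD and BR3 mean, plus the QC mask, a
#'   convergence mask, and a tibble of per-voxel summaries. Counts of
#'   fitted / skipped / non-converged voxels are attached as attributes.
#' @export
fit_volume <- function(voxels, grid, prior = prior_spec(),
                       control = sampler_control(chains = 2L, warmup = 500L,
                                                 iter = 500L),
                       seed = 1L, fit_range = c(-2, 8),
                       include_nonconverged = FALSE) {
  dims <- grid$dims
  shape <- function() array(NA_real_, dims)
  tau3_map <- shape(); sd_map <- shape(); br3_map <- shape()
  qc_mask <- array(FALSE, dims)
  conv_mask <- array(NA, dims)

  lin_idx <- (voxels$ix - 1L) + dims[1] * ((voxels$iy - 1L) +
                                             dims[2] * (voxels$iz - 1L))
  fits <- purrr::pmap(
    list(voxels$tdd, voxels$qc_pass, lin_idx),
    function(tdd, qc, li) {
      if (!qc) return(NULL)
      A <- compute_A(tdd, fit_range)
      if (!attr(A, "fittable")) return(NULL)
      vseed <- (as.double(seed) * 48271 + as.double(li)) %% 2147483647
      fit_tdd(tdd, prior, control, seed = as.integer(vseed), fit_range)
    }
  )

  rows <- purrr::pmap(
    list(seq_len(nrow(voxels)), fits),
    function(i, f) {
      ix <- voxels$ix[i]; iy <- voxels$iy[i]; iz <- voxels$iz[i]
      qc_mask[ix, iy, iz] <<- voxels$qc_pass[i]
      if (is.null(f)) {
        return(tibble::tibble(ix = ix, iy = iy, iz = iz, n = voxels$n[i],
                              fitted = FALSE, converged = NA,
                              tau3_mean = NA_real_, tau3_sd = NA_real_,
                              br3_mean = NA_real_))
      }
      conv_mask[ix, iy, iz] <<- f$converged
      if (f$converged || include_nonconverged) {
        tau3_map[ix, iy, iz] <<- f$summary$tau3_mean
        sd_map[ix, iy, iz] <<- f$summary$tau3_sd
        br3_map[ix, iy, iz] <<- f$summary$br_mean[3]
      }
      tibble::tibble(ix = ix, iy = iy, iz = iz, n = voxels$n[i],
                     fitted = TRUE, converged = f$converged,
                     tau3_mean = f$summary$tau3_mean,
                     tau3_sd = f$summary$tau3_sd,
                     br3_mean = f$summary$br_mean[3])
    }
  ) |> dplyr::bind_rows()

  lifetime_image(grid, tau3_map, sd_map, br3_map, qc_mask, conv_mask,
                 fits = rows,
                 provenance = list(seed = seed,
                                   control = unclass(control),
                                   fit_range = fit_range,
                                   n_fitted = sum(rows$fitted),
                                   n_skipped = sum(!rows$fitted),
                                   n_nonconverged =
                                     sum(rows$fitted & !rows$converged)))
}
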