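#' Sample positron decays from a digital phantom
#'
#' Draws emission events from each tube of the phantom: decay counts are
#' Poisson with mean `activity * duration * positron_fraction`, decay
#' positions are uniform inside the tube, decay times uniform over the
#' acquisition, the annihilation channel (pPs / direct / oPs) is sampled
#' from the material branching fractions, and the annihilation delay is
#' exponential with the channel lifetime. Electron-capture decays are not
#' generated; the prompt photon is attached per positron with probability
#' `scanner$prompt_br_per_positron`.
#'
#' @param phantom list of [tube_region()] objects; tubes must not overlap.
#' @param duration acquisition time in seconds (> 0).
#' @param scanner a [scanner_spec()].
#' @param seed optional integer seed.
#' @return A tibble with one row per positron decay: `x`, `y`, `z` (mm),
#'   `t_ns` (decay time), `channel`, `delay_ns`, `has_prompt`, `tube`,
#'   `event_id`.
#' @export
sample_decays <- function(phantom, duration, scanner = scanner_spec(),
                          seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be a positive number of seconds")
  }
  if (!any(purrr::map_dbl(phantom, "activity") > 0)) {
    stop("at least one tube must have positive activity")
  }
  check_no_overlap(phantom)
  if (!is.null(seed)) set.seed(seed)

  per_tube <- purrr::map(phantom, function(tb) {
    mean_n <- tb$activity * 1e6 * duration * scanner$positron_fraction
    n <- stats::rpois(1L, mean_n)
    if (n == 0L) {
      return(tibble::tibble(x = double(), y = double(), z = double(),
                            t_ns = double(), channel = character(),
                            delay_ns = double(), has_prompt = logical(),
                            tube = character()))
    }
    pos <- runif_cylinder(n, tb)
    taus <- c(TAU1_PPS, TAU2_DIRECT, tb$material$tau3)
    ch <- sample.int(3L, n, replace = TRUE, prob = tb$material$br)
    tibble::tibble(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      t_ns = stats::runif(n, 0, duration * 1e9),
      channel = c("pPs", "direct", "oPs")[ch],
      delay_ns = stats::rexp(n, rate = 1 / taus[ch]),
      has_prompt = stats::runif(n) < scanner$prompt_br_per_positron,
      tube = tb$label
    )
  })
  out <- dplyr::bind_rows(per_tube)
  out$event_id <- seq_len(nrow(out))
  out
}

# uniform points inside a finite cylinder with arbitrary unit axis
runif_cylinder <- function(n, tube) {
  r <- tube$radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  h <- stats::runif(n, -tube$half_length, tube$half_length)
  basis <- orthonormal_basis(tube$axis)
  local <- cbind(r * cos(phi), r * sin(phi), h)
  sweep(local %*% t(basis), 2, tube$center, `+`)
}

# columns: two unit vectors orthogonal to `axis`, then `axis`
orthonormal_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2, axis)
}

check_no_overlap <- function(phantom) {
  nt <- length(phantom)
  if (nt < 2L) return(invisible(TRUE))
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      a <- phantom[[i]]; b <- phantom[[j]]
      d <- b$center - a$center
      if (sum(abs(a$axis - b$axis)) < 1e-12) {
        dz <- abs(sum(d * a$axis))
        dr <- sqrt(max(0, sum(d^2) - sum(d * a$axis)^2))
        overlap <- dz < a$half_length + b$half_length &&
          dr < a$radius + b$radius
      } else {
        # conservative bounding-sphere test for non-parallel axes
        ra <- sqrt(a$radius^2 + a$half_length^2)
        rb <- sqrt(b$radius^2 + b$half_length^2)
        overlap <- sqrt(sum(d^2)) < ra + rb
      }
      if (overlap) stop("tubes '", a$label, "' and '", b$label, "' overlap")
    }
  }
  invisible(TRUE)
}

#' Detect the photons of emission events on the scanner cylinder
#'
#' For each decay, two 511 keV annihilation photons are emitted
#' back-to-back in an isotropic direction from the decay position at
#' `t_ns + delay_ns` (positron range and acollinearity are neglected), and,
#' when `has_prompt` is set, one 602.73 keV prompt photon is emitted
#' isotropically at the decay time. Photons are intersected with the
#' detector barrel; hits receive Gaussian timing smear (`timing_sigma`) and
#' a Gaussian relative energy smear scaling as sqrt(511 keV / E) from the
#' fractional FWHM at 511 keV. Photons that miss the barrel are dropped.
#'
#' @param decays tibble from [sample_decays()].
#' @param scanner a [scanner_spec()].
#' @param seed optional integer seed.
#' @return Singles tibble: `x_mm`, `y_mm`, `z_mm` (crystal position),
#'   `t_ns`, `E_keV`, `tag` (`"annih"` or `"prompt"`), `event_id`. Rows are
#'   unordered; sort by time before event selection.
#' @export
emit_and_detect <- function(decays, scanner = scanner_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(decays)
  if (n == 0L) return(empty_singles())

  src <- as.matrix(decays[, c("x", "y", "z")])
  inside <- sqrt(src[, 1]^2 + src[, 2]^2) < scanner$ring_radius &
    abs(src[, 3]) < scanner$axial_half_length
  if (!all(inside)) stop("emission events outside the scanner bore")

  dir <- runif_sphere(n)
  t_ann <- decays$t_ns + decays$delay_ns
  hit_a <- cylinder_hit(src, dir, scanner)
  hit_b <- cylinder_hit(src, -dir, scanner)

  singles <- list(
    detect_photons(src, hit_a, t_ann, 511, decays$event_id, "annih", scanner),
    detect_photons(src, hit_b, t_ann, 511, decays$event_id, "annih", scanner)
  )
  ip <- which(decays$has_prompt)
  if (length(ip)) {
    dir_p <- runif_sphere(length(ip))
    hit_p <- cylinder_hit(src[ip, , drop = FALSE], dir_p, scanner)
    singles[[3L]] <- detect_photons(src[ip, , drop = FALSE], hit_p,
                                    decays$t_ns[ip], 602.73,
                                    decays$event_id[ip], "prompt", scanner)
  }
  dplyr::bind_rows(singles)
}

empty_singles <- function() {
  tibble::tibble(x_mm = double(), y_mm = double(), z_mm = double(),
                 t_ns = double(), E_keV = double(), tag = character(),
                 event_id = integer())
}

runif_sphere <- function(n) {
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - cz^2)
  cbind(s * cos(phi), s * sin(phi), cz)
}

# first intersection of rays p + s*d with the barrel; NA distance on miss
cylinder_hit <- function(p, d, scanner) {
  R <- scanner$ring_radius
  a <- d[, 1]^2 + d[, 2]^2
  b <- p[, 1] * d[, 1] + p[, 2] * d[, 2]
  c0 <- p[, 1]^2 + p[, 2]^2 - R^2
  disc <- b^2 - a * c0
  s <- ifelse(a > 1e-12, (-b + sqrt(pmax(disc, 0))) / a, NA_real_)
  z <- p[, 3] + s * d[, 3]
  s[!is.na(z) & abs(z) > scanner$axial_half_length] <- NA_real_
  pos <- p + s * d
  list(pos = pos, dist = s)
}

detect_photons <- function(src, hit, t_emit, e_true, event_id, tag, scanner) {
  keep <- which(!is.na(hit$dist))
  if (!length(keep)) return(empty_singles())
  dist <- hit$dist[keep]
  t <- t_emit[keep] + dist / C_MM_PER_NS +
    stats::rnorm(length(keep), 0, scanner$timing_sigma)
  e <- e_true * (1 + stats::rnorm(length(keep), 0, energy_rel_sigma(e_true, scanner)))
  tibble::tibble(
    x_mm = hit$pos[keep, 1], y_mm = hit$pos[keep, 2], z_mm = hit$pos[keep, 3],
    t_ns = t, E_keV = e, tag = tag, event_id = event_id[keep]
  )
}

energy_rel_sigma <- function(e_true, scanner) {
  scanner$energy_fwhm_frac_511 / (2 * sqrt(2 * log(2))) * sqrt(511 / e_true)
}

#' Inject random three-photon coincidences into a singles stream
#'
#' A random coincidence is a genuine annihilation photon pair accompanied
#' by an uncorrelated prompt photon (from a different decay), so its TOF
#' vertex follows the activity distribution while its time difference
#' carries no lifetime information. Injected triples reproduce this: when
#' a `phantom` is supplied the pair is emitted back-to-back from an
#' activity-weighted position inside the tubes (with the usual timing
#' smear); otherwise the pair is placed at random barrel crystals. The
#' prompt detection time is back-solved through the same TOF arithmetic
#' the selection uses so that the analysis time difference of the triple
#' is uniform over `scanner$randoms_dt_window` -- the flat background the
#' fixed-background estimator assumes. The number of triples is set so
#' the accepted three-photon stream contains, in expectation, the
#' fraction `scanner$randoms_rate_frac` of randoms.
#'
#' @param singles time-sorted singles tibble.
#' @param scanner a [scanner_spec()].
#' @param seed optional integer seed.
#' @param windows [energy_windows()] used downstream (randoms are drawn
#'   inside these windows).
#' @param coincidence_width coincidence window (ns) used downstream, to
#'   count the true accepted events the fraction refers to.
#' @param phantom optional list of [tube_region()]; when given, random
#'   pairs originate from activity-weighted positions in the tubes.
#' @return Singles tibble including the injected records (`tag =
#'   "random"`), sorted by time.
#' @export
inject_randoms <- function(singles, scanner = scanner_spec(), seed = NULL,
                           windows = energy_windows(),
                           coincidence_width = 15, phantom = NULL) {
  frac <- scanner$randoms_rate_frac
  if (frac == 0 || nrow(singles) == 0L) {
    return(dplyr::arrange(singles, .data$t_ns))
  }
  if (!is.null(seed)) set.seed(seed)
  n_true <- nrow(build_3g_events(dplyr::arrange(singles, .data$t_ns),
                                 windows, coincidence_width))
  n_rand <- round(n_true * frac / (1 - frac))
  if (n_rand == 0L) return(dplyr::arrange(singles, .data$t_ns))

  t0 <- stats::runif(n_rand, min(singles$t_ns), max(singles$t_ns))
  if (is.null(phantom)) {
    pa <- runif_barrel(n_rand, scanner)
    pb <- runif_barrel(n_rand, scanner)
    ta <- t0
    tb <- t0 + stats::rnorm(n_rand, 0, sqrt(2) * max(scanner$timing_sigma, 0.05))
  } else {
    cry <- random_pair_crystals(n_rand, phantom, scanner)
    pa <- cry$pa
    pb <- cry$pb
    ta <- t0 + cry$da / C_MM_PER_NS +
      stats::rnorm(n_rand, 0, scanner$timing_sigma)
    tb <- t0 + cry$db / C_MM_PER_NS +
      stats::rnorm(n_rand, 0, scanner$timing_sigma)
  }
  pp <- runif_barrel(n_rand, scanner)

  v <- localize_tof(pa, ta, pb, tb)
  da <- row_dist(pa, v); db <- row_dist(pb, v); dp <- row_dist(pp, v)
  t_ann <- 0.5 * ((ta - da / C_MM_PER_NS) + (tb - db / C_MM_PER_NS))
  dt_target <- stats::runif(n_rand, scanner$randoms_dt_window[1],
                            scanner$randoms_dt_window[2])
  tp <- t_ann - dt_target + dp / C_MM_PER_NS

  rand <- tibble::tibble(
    x_mm = c(pa[, 1], pb[, 1], pp[, 1]),
    y_mm = c(pa[, 2], pb[, 2], pp[, 2]),
    z_mm = c(pa[, 3], pb[, 3], pp[, 3]),
    t_ns = c(ta, tb, tp),
    E_keV = c(runif_window(n_rand, 511, windows$annihilation, scanner),
              runif_window(n_rand, 511, windows$annihilation, scanner),
              runif_window(n_rand, 602.73, windows$prompt, scanner)),
    tag = rep("random", 3L * n_rand),
    event_id = rep(NA_integer_, 3L * n_rand)
  )
  dplyr::arrange(dplyr::bind_rows(singles, rand), .data$t_ns)
}

# crystals hit by back-to-back pairs emitted from activity-weighted
# positions in the tubes (rejection on barrel acceptance)
random_pair_crystals <- function(n, phantom, scanner) {
  acts <- purrr::map_dbl(phantom, "activity")
  pa <- matrix(NA_real_, n, 3L); pb <- matrix(NA_real_, n, 3L)
  da <- numeric(n); db <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    n_tube <- as.vector(stats::rmultinom(1L, m, acts / sum(acts)))
    src <- do.call(rbind, purrr::map2(phantom, n_tube, function(tb, k) {
      if (k == 0L) matrix(numeric(), 0L, 3L) else runif_cylinder(k, tb)
    }))
    dir <- runif_sphere(m)
    ha <- cylinder_hit(src, dir, scanner)
    hb <- cylinder_hit(src, -dir, scanner)
    got <- !is.na(ha$dist) & !is.na(hb$dist)
    idx <- need[got]
    pa[idx, ] <- ha$pos[got, , drop = FALSE]
    pb[idx, ] <- hb$pos[got, , drop = FALSE]
    da[idx] <- ha$dist[got]
    db[idx] <- hb$dist[got]
    need <- need[!got]
  }
  list(pa = pa, pb = pb, da = da, db = db)
}

runif_barrel <- function(n, scanner) {
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(scanner$ring_radius * cos(phi), scanner$ring_radius * sin(phi),
        stats::runif(n, -scanner$axial_half_length, scanner$axial_half_length))
}

row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

# smeared photopeak energies truncated to a window (vectorized rejection)
runif_window <- function(n, e_true, window, scanner) {
  sd <- e_true * energy_rel_sigma(e_true, scanner)
  lo <- stats::pnorm(window[1], e_true, sd)
  hi <- stats::pnorm(window[2], e_true, sd)
  stats::qnorm(stats::runif(n, lo, hi), e_true, sd)
}

#' Simulate a singles list-mode table end to end
#'
#' Convenience wrapper: [sample_decays()], [emit_and_detect()], time sort,
#' then [inject_randoms()].
#'
#' @inheritParams sample_decays
#' @inheritParams inject_randoms
#' @return Time-sorted singles tibble with attribute `"decays"` holding the
#'   generative emission table (for truth-level validation).
#' @export
simulate_singles <- function(phantom, duration, scanner = scanner_spec(),
                             seed = NULL, windows = energy_windows(),
                             coincidence_width = 15) {
  if (!is.null(seed)) set.seed(seed)
  decays <- sample_decays(phantom, duration, scanner)
  singles <- emit_and_detect(decays, scanner)
  singles <- dplyr::arrange(singles, .data$t_ns)
  singles <- inject_randoms(singles, scanner, windows = windows,
                            coincidence_width = coincidence_width,
                            phantom = phantom)
  attr(singles, "decays") <- decays
  singles
}

#' Directly sample a time-difference spectrum
#'
#' Fast path bypassing photon transport: signal values are an exponential
#' channel delay (channel drawn from `br`, lifetimes `tau1`, `tau2`,
#' `tau3`) plus Gaussian resolution noise `N(delta, sigma)`; background
#' values are uniform over `window`.
#'
#' @param tau3 oPs lifetime (ns).
#' @param br length-3 branching fractions summing to 1.
#' @param sigma Gaussian resolution sigma (ns).
#' @param delta time offset (ns).
#' @param n_signal,n_background numbers of signal / background values.
#' @param window length-2 support (ns) of the uniform background.
#' @param tau1,tau2 fixed pPs and direct-annihilation lifetimes (ns).
#' @param seed optional integer seed.
#' @return Numeric vector of `n_signal + n_background` time differences.
#' @export
sample_tdd_direct <- function(tau3, br, sigma = 0.12, delta = 0,
                              n_signal, n_background = 0,
                              window = c(-5, 8),
                              tau1 = TAU1_PPS, tau2 = TAU2_DIRECT,
                              seed = NULL) {
  stopifnot(n_signal >= 0, n_background >= 0, window[1] < window[2])
  if (abs(sum(br) - 1) > 1e-12) stop("br must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  sig <- if (n_signal > 0) {
    taus <- c(tau1, tau2, tau3)
    ch <- sample.int(3L, n_signal, replace = TRUE, prob = br)
    stats::rexp(n_signal, 1 / taus[ch]) + stats::rnorm(n_signal, delta, sigma)
  } else double()
  bkg <- if (n_background > 0) {
    stats::runif(n_background, window[1], window[2])
  } else double()
  c(sig, bkg)
}

#' Directly sample selected three-photon events
#'
#' Vertex-level fast path mirroring [sample_tdd_direct()]: produces the
#' table that selection of a full singles stream would yield, without
#' photon transport. True vertices are uniform inside the tubes (tube
#' share proportional to activity); the TOF localization error is Gaussian
#' with sigma `(c/2) * sqrt(2) * timing_sigma` along an isotropic
#' line-of-response direction; the time difference is the channel delay
#' plus Gaussian noise of sigma `sqrt(5/3) * timing_sigma` (three smeared
#' detection times entering the vertex-corrected difference). Randoms are
#' added at the scanner's `randoms_rate_frac`: their annihilation pair is
#' real, so their vertices follow the same activity-weighted, TOF-blurred
#' distribution as the signal, while their time difference is uniform
#' over `randoms_dt_window`.
#'
#' @param phantom list of [tube_region()].
#' @param n_events number of signal (true) events.
#' @param scanner a [scanner_spec()].
#' @param seed optional integer seed.
#' @return Tibble `vx`, `vy`, `vz` (mm), `delta_t` (ns), `tag`, `tube`.
#' @export
sample_events_direct <- function(phantom, n_events,
                                 scanner = scanner_spec(), seed = NULL) {
  stopifnot(n_events >= 0)
  if (!is.null(seed)) set.seed(seed)
  acts <- purrr::map_dbl(phantom, "activity")
  stopifnot(any(acts > 0))
  n_tube <- as.vector(stats::rmultinom(1L, n_events, acts / sum(acts)))
  sigma_loc <- (C_MM_PER_NS / 2) * sqrt(2) * scanner$timing_sigma
  sigma_dt <- sqrt(5 / 3) * scanner$timing_sigma

  per_tube <- purrr::map2(phantom, n_tube, function(tb, n) {
    if (n == 0L) {
      return(tibble::tibble(vx = double(), vy = double(), vz = double(),
                            delta_t = double(), tag = character(),
                            tube = character()))
    }
    pos <- runif_cylinder(n, tb)
    taus <- c(TAU1_PPS, TAU2_DIRECT, tb$material$tau3)
    ch <- sample.int(3L, n, replace = TRUE, prob = tb$material$br)
    delay <- stats::rexp(n, 1 / taus[ch])
    u <- runif_sphere(n)
    shift <- stats::rnorm(n, 0, sigma_loc)
    tibble::tibble(
      vx = pos[, 1] + shift * u[, 1],
      vy = pos[, 2] + shift * u[, 2],
      vz = pos[, 3] + shift * u[, 3],
      delta_t = delay + stats::rnorm(n, 0, sigma_dt),
      tag = "annih", tube = tb$label
    )
  })
  out <- dplyr::bind_rows(per_tube)

  frac <- scanner$randoms_rate_frac
  n_rand <- round(n_events * frac / (1 - frac))
  if (n_rand > 0L) {
    n_tube_r <- as.vector(stats::rmultinom(1L, n_rand, acts / sum(acts)))
    pos_r <- do.call(rbind, purrr::map2(phantom, n_tube_r, function(tb, k) {
      if (k == 0L) matrix(numeric(), 0L, 3L) else runif_cylinder(k, tb)
    }))
    u_r <- runif_sphere(n_rand)
    shift_r <- stats::rnorm(n_rand, 0, sigma_loc)
    rnd <- tibble::tibble(
      vx = pos_r[, 1] + shift_r * u_r[, 1],
      vy = pos_r[, 2] + shift_r * u_r[, 2],
      vz = pos_r[, 3] + shift_r * u_r[, 3],
      delta_t = stats::runif(n_rand, scanner$randoms_dt_window[1],
                             scanner$randoms_dt_window[2]),
      tag = "random", tube = NA_character_
    )
    out <- dplyr::bind_rows(out, rnd)
  }
  out
}

#' Write / read a singles table as CSV
#'
#' Plain-text list-mode exchange format: a `#`-prefixed schema header line
#' followed by the columns `x_mm, y_mm, z_mm, t_ns, E_keV, tag`.
#'
#' @param singles singles tibble.
#' @param path file path.
#' @return `read_singles()` returns the singles tibble.
#' @export
write_singles <- function(singles, path) {
  readr::write_lines("# pslife singles v1", path)
  readr::write_csv(singles[, c("x_mm", "y_mm", "z_mm", "t_ns", "E_keV", "tag")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_singles
#' @export
read_singles <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    x_mm = "d", y_mm = "d", z_mm = "d",
                    t_ns = "d", E_keV = "d", tag = "c"))
}
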