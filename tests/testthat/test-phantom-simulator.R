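test_that("constructors validate physical invariants", {
  expect_error(material_spec(-1, c(0, 0, 1)), "tau3")
  expect_error(material_spec(2, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(tube_region(c(0, 0, 0), 7.5, 14, 1, material_spec(2, c(0, 0, 1)),
                           axis = c(0, 0, 2)), "unit norm")
  expect_error(scanner_spec(randoms_rate_frac = 1.2))
  expect_error(sample_decays(xad4_phantom(), duration = -1), "positive")
  ph0 <- lapply(xad4_phantom(), function(tb) { tb$activity <- 0; tb })
  expect_error(sample_decays(ph0, 1), "positive activity")
  over <- list(xad4_phantom()[[1]],
               local({ tb <- xad4_phantom()[[1]]; tb$center <- tb$center + 1
                       tb$label <- "b"; tb }))
  expect_error(sample_decays(over, 1), "overlap")
})

test_that("zero-activity tubes produce no decays", {
  ph <- xad4_phantom()
  ph[[2]]$activity <- 0
  d <- sample_decays(ph, duration = 1e-3, seed = 1)
  expect_false(any(d$tube == "T2_wet"))
  expect_gt(nrow(d), 0)
})

test_that("decay sampling reproduces the generative channel model", {
  tb <- tube_region(c(0, 0, 0), 7.5, 14.1, 10, material_spec(2.0, c(0, 0, 1)),
                    label = "pure_oPs")
  sc <- scanner_spec()
  n_target <- 1e5
  dur <- n_target / (10e6 * sc$positron_fraction)
  d <- sample_decays(list(tb), dur, sc, seed = 11)
  n <- nrow(d)
  expect_gt(n, n_target * 0.97)
  # Exp(tau) delays: sample mean within 3 CLT standard errors of tau
  expect_lt(abs(mean(d$delay_ns) - 2.0), 3 * 2.0 / sqrt(n))
  expect_true(all(d$channel == "oPs"))
  # positions uniform inside the tube
  r <- sqrt(d$x^2 + d$y^2)
  expect_lte(max(r), 7.5)
  expect_lte(max(abs(d$z)), 14.1)
  expect_lt(abs(mean(r^2) - 7.5^2 / 2), 3 * stats::sd(r^2) / sqrt(n))
  # prompt attachment is Bernoulli(0.12)
  expect_lt(abs(mean(d$has_prompt) - 0.12), 3 * sqrt(0.12 * 0.88 / n))
})

test_that("channel frequencies match the branching fractions", {
  br <- t4_br()
  tb <- tube_region(c(0, 0, 0), 7.5, 14.1, 10, material_spec(1.82, br))
  sc <- scanner_spec()
  d <- sample_decays(list(tb), 1e5 / (10e6 * sc$positron_fraction), sc,
                     seed = 12)
  n <- nrow(d)
  freq <- table(factor(d$channel, c("pPs", "direct", "oPs"))) / n
  for (k in 1:3) {
    expect_lt(abs(freq[[k]] - br[k]), 3 * sqrt(br[k] * (1 - br[k]) / n))
  }
})

test_that("noiseless detection is geometrically exact", {
  sc <- noiseless_scanner()
  dec <- tibble::tibble(x = 0, y = 0, z = 0, t_ns = 100, channel = "oPs",
                        delay_ns = 1.5, has_prompt = TRUE,
                        tube = "pt", event_id = 1L)
  s <- emit_and_detect(dec[rep(1, 200), ] |>
                         dplyr::mutate(event_id = 1:200), sc, seed = 3)
  ann <- s[s$tag == "annih", ]
  # a vertex at the scanner centre gives antipodal crystals and equal times
  pairs <- split(ann, ann$event_id)
  pairs <- pairs[vapply(pairs, nrow, 1L) == 2L]
  expect_gt(length(pairs), 100)
  for (p in pairs[1:20]) {
    expect_equal(p$x_mm[1], -p$x_mm[2], tolerance = 1e-9)
    expect_equal(p$y_mm[1], -p$y_mm[2], tolerance = 1e-9)
    expect_equal(p$z_mm[1], -p$z_mm[2], tolerance = 1e-9)
    expect_equal(p$t_ns[1], p$t_ns[2], tolerance = 1e-12)
  }
  # unsmeared energies sit exactly on the photopeaks
  expect_true(all(abs(ann$E_keV - 511) < 1e-12))
  pr <- s[s$tag == "prompt", ]
  expect_true(all(abs(pr$E_keV - 602.73) < 1e-12))
  # crystals lie on the detector barrel
  expect_true(all(abs(sqrt(s$x_mm^2 + s$y_mm^2) - sc$ring_radius) < 1e-6))
})

test_that("randoms injection controls the accepted-event fraction", {
  ph <- xad4_phantom()
  sc0 <- scanner_spec(randoms_rate_frac = 0)
  sc2 <- scanner_spec(randoms_rate_frac = 0.2)
  set.seed(5)
  dec <- sample_decays(ph, 0.05, sc2)
  singles <- dplyr::arrange(emit_and_detect(dec, sc2), t_ns)
  expect_identical(nrow(inject_randoms(singles, sc0)), nrow(singles))
  s2 <- inject_randoms(singles, sc2, phantom = ph)
  ev <- build_3g_events(s2)
  fr <- mean(ev$tag == "random")
  n <- nrow(ev)
  expect_gt(n, 2000)
  expect_lt(abs(fr - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # the background region of the spectrum is flat
  bg <- ev$delta_t[ev$delta_t >= -5 & ev$delta_t < -2.6]
  h <- graphics::hist(bg, breaks = seq(-5, -2.6, by = 0.2), plot = FALSE)
  expect_gt(stats::chisq.test(h$counts)$p.value, 0.01)
})

test_that("direct TDD sampling matches its closed-form moments", {
  expect_error(sample_tdd_direct(2, c(0.5, 0.4, 0.2), n_signal = 10),
               "sum to 1")
  # pure background is uniform
  x <- sample_tdd_direct(2, c(0, 0, 1), n_signal = 0, n_background = 1e4,
                         window = c(-5, 8), seed = 1)
  ks <- stats::ks.test(x, "punif", -5, 8)
  expect_gt(ks$p.value, 0.01)
  # degenerate resolution: pure exponential of mean tau3
  y <- sample_tdd_direct(2, c(0, 0, 1), sigma = 1e-6, n_signal = 1e5,
                         seed = 2)
  expect_lt(abs(mean(y) - 2), 3 * 2 / sqrt(1e5))
  # T1 parameters: mean is delta + sum BR_k tau_k
  br <- c(0.073, 0.716, 0.211); br <- br / sum(br)
  z <- sample_tdd_direct(2.52, br, sigma = 0.12, n_signal = 1e5, seed = 3)
  mu <- sum(br * c(0.125, 0.388, 2.52))
  expect_lt(abs(mean(z) - mu), 3 * stats::sd(z) / sqrt(1e5))
})

test_that("the noiseless time-difference spectrum is the generative mixture", {
  br <- t4_br()
  x <- sample_tdd_direct(1.82, br, sigma = 1e-9, n_signal = 1e5, seed = 4)
  expect_true(all(x >= -1e-6))
  pmix <- function(q) {
    taus <- c(0.125, 0.388, 1.82)
    rowSums(vapply(1:3, function(k) br[k] * stats::pexp(q, 1 / taus[k]),
                   numeric(length(q))))
  }
  ks <- stats::ks.test(x, pmix)
  expect_gt(ks$p.value, 0.01)
})

test_that("seeded simulation is bit-reproducible", {
  ph <- quiet_phantom()
  a <- simulate_singles(ph, 1e-3, scanner_spec(), seed = 42)
  b <- simulate_singles(ph, 1e-3, scanner_spec(), seed = 42)
  expect_identical(a, b)
  x <- sample_events_direct(ph, 1000, seed = 9)
  y <- sample_events_direct(ph, 1000, seed = 9)
  expect_identical(x, y)
})

test_that("singles tables round-trip through CSV", {
  s <- simulate_singles(quiet_phantom(), 1e-3, scanner_spec(), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_singles(s, path)
  r <- read_singles(path)
  expect_equal(r$t_ns, s$t_ns)
  expect_equal(r$E_keV, s$E_keV)
  expect_identical(r$tag, s$tag)
})
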