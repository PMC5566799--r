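test_that("firing rates and their population moments are computed correctly", {
  sp <- tibble::tibble(neuron = rep(0L, 10), time_ms = seq(50, 950, length.out = 10))
  rs <- firing_rates(sp, interval_ms = c(0, 1000), n_neurons = 1)
  expect_equal(rs$rates$rate, 10)

  sp2 <- tibble::tibble(neuron = rep(0:4, each = 3),
                        time_ms = rep(c(100, 400, 900), 5))
  rs2 <- firing_rates(sp2, interval_ms = c(0, 1000), n_neurons = 5)
  expect_equal(rs2$sd, 0)
  expect_true(is.na(rs2$skewness))
  expect_error(firing_rates(sp2, interval_ms = c(500, 500), n_neurons = 5),
               "zero-length")

  # lognormal rates: skewness recovered within 10% of (e^{s2}+2)sqrt(e^{s2}-1)
  set.seed(2)
  s <- 0.5
  n <- 1e4
  rates <- stats::rlnorm(n, meanlog = 2, sdlog = s)
  spl <- tibble::tibble(neuron = rep(0:(n - 1L), times = round(rates)),
                        time_ms = 500)
  rsl <- firing_rates(spl, interval_ms = c(0, 1000), n_neurons = n)
  skew_true <- (exp(s^2) + 2) * sqrt(exp(s^2) - 1)
  # rounding to counts adds noise; Poissonised draw keeps it within 10%
  expect_lt(abs(rsl$skewness - skew_true) / skew_true, 0.10)
})

test_that("CV of interspike intervals matches closed-form cases", {
  expect_equal(cv_isi(seq(0, 1000, by = 10)), 0)
  expect_true(is.na(cv_isi(c(1, 2))))

  # alternating intervals a, 3a: mean 2a, sd a (population) -> CV 0.5
  t_alt <- cumsum(rep(c(1, 3), 2000))
  isi <- diff(t_alt)
  expect_equal(stats::sd(isi) / mean(isi), cv_isi(t_alt))
  expect_equal(cv_isi(t_alt), 0.5, tolerance = 1e-3)

  set.seed(3)
  pois <- cumsum(stats::rexp(1e4, 1))
  expect_equal(cv_isi(pois), 1, tolerance = 0.03)
})

test_that("gamma-ISI renewal trains recover CV = 1/sqrt(shape) within 5%", {
  set.seed(4)
  for (shape in c(0.5, 2, 5)) {
    train <- cumsum(stats::rgamma(1e4, shape = shape, rate = shape))
    expect_equal(cv_isi(train), 1 / sqrt(shape), tolerance = 0.05)
  }
})

test_that("delta_response is the evoked/background ratio with a guarded zero case", {
  expect_equal(delta_response(5, 5), 1)
  expect_equal(delta_response(10, 2), 5)
  expect_true(is.na(delta_response(3, 0)))
})

test_that("Fano factor across trials matches hand-computed and Poisson references", {
  expect_error(fano_factor(matrix(1, nrow = 1, ncol = 3)), "at least 2 trials")

  same <- matrix(7, nrow = 5, ncol = 4)
  expect_true(all(fano_factor(same)$fano == 0))

  two <- matrix(c(2, 4), nrow = 2, ncol = 1)
  expect_equal(fano_factor(two)$fano, 2 / 3)

  set.seed(5)
  pois <- matrix(stats::rpois(1000 * 4, lambda = 20), nrow = 1000)
  ff <- fano_factor(pois)
  expect_true(all(abs(ff$fano - 1) < 0.1))

  zero <- matrix(0, nrow = 3, ncol = 2)
  fz <- fano_factor(zero)
  expect_true(all(fz$zero_mean))
  expect_true(all(is.na(fz$fano)))
})

test_that("correlation spectra behave for identical, independent and degenerate trains", {
  dur <- 1e5
  set.seed(6)
  tA <- poisson_input_stream(50, dur)
  mk_res <- function(trains) {
    sp <- dplyr::bind_rows(lapply(seq_along(trains), function(i)
      tibble::tibble(neuron = i - 1L, time_ms = trains[[i]])))
    striatnet:::fixture_result(sp, length(trains), dur)
  }
  # identical trains: correlation exactly 1
  cs <- correlation_spectrum(mk_res(list(tA, tA)), bin_ms = 100)
  expect_equal(cs$pairs$correlation, 1)

  # independent trains: coefficients centred at zero (1000 bins per pair)
  trains <- lapply(1:12, function(i) poisson_input_stream(50, dur))
  csi <- correlation_spectrum(mk_res(trains), bin_ms = 100)
  expect_identical(nrow(csi$pairs), 66L)
  expect_lt(abs(mean(csi$pairs$correlation)), 0.02)
  expect_true(all(abs(csi$pairs$correlation) <= 1))

  # zero-variance neurons are excluded and counted
  silent <- mk_res(list(tA, numeric(0), poisson_input_stream(50, dur)))
  css <- correlation_spectrum(silent, bin_ms = 100)
  expect_identical(css$n_excluded, 1L)
  expect_identical(nrow(css$pairs), 1L)

  # invariant under neuron relabeling
  csr <- correlation_spectrum(mk_res(rev(trains)), bin_ms = 100)
  expect_equal(sort(csr$pairs$correlation), sort(csi$pairs$correlation))
})

test_that("state classification follows the count/lifespan rules", {
  geom <- grid_geometry(50, 50)
  mk <- function(cx, cy) tibble::tibble(bump = seq_along(cx), cx = cx, cy = cy,
                                        n_pixels = 5L, peak_activity = 1,
                                        members = vector("list", length(cx)))
  empty_sets <- replicate(60, mk(numeric(0), numeric(0)), simplify = FALSE)
  tr0 <- track_bumps(empty_sets, geom, window_ms = 100)
  expect_identical(as.character(classify_state(tr0, empty_sets)$state), "AI")

  persistent <- replicate(60, mk(c(10, 30), c(10, 30)), simplify = FALSE)
  trp <- track_bumps(persistent, geom, link_radius = 3, window_ms = 100)
  expect_identical(as.character(classify_state(trp, persistent)$state), "WTA")

  # bumps present but each lives a single frame -> TA
  set.seed(7)
  flicker <- lapply(1:60, function(f) mk(runif(3, 0, 49), runif(3, 0, 49)))
  trf <- track_bumps(flicker, geom, link_radius = 1e-6, window_ms = 100)
  expect_identical(as.character(classify_state(trf, flicker)$state), "TA")

  short <- persistent[1:10]
  trs <- track_bumps(short, geom, window_ms = 100)
  expect_error(classify_state(trs, short), "at least")
})
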