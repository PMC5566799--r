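test_that("stimulated-neuron selection concentrates around the centre and respects exclusions", {
  geom <- grid_geometry(100, 100)
  set.seed(1)
  # n = 1: the modal pick over repeated draws sits at (or right next to) the
  # centre — the sampling law's mode is the centre neuron
  picks <- replicate(600, select_stimulated_neurons(c(50, 50), sigma = 2, n = 1, geom))
  top <- as.integer(names(which.max(table(picks))))
  txy <- xy_from_idx(top, geom)
  expect_lte(torus_distance(txy$x, txy$y, 50, 50, geom), 1.5)
  # and the centre neuron is picked far more often than a 2-sigma site
  tab <- table(factor(picks, levels = 0:(geom$n - 1)))
  expect_gt(tab[[as.character(idx_from_xy(50, 50, geom))]],
            tab[[as.character(idx_from_xy(50, 54, geom))]])

  # n = 45, sigma = 2: >= 90% of picks within 3 sigma of the centre
  sel <- select_stimulated_neurons(c(50, 50), sigma = 2, n = 45, geom)
  expect_identical(length(unique(sel)), 45L)
  xy <- xy_from_idx(sel, geom)
  d <- torus_distance(xy$x, xy$y, 50, 50, geom)
  expect_gte(mean(d <= 6), 0.9)

  # two centres 10 apart: disjoint sets by construction
  a <- select_stimulated_neurons(c(45, 50), 2, 45, geom)
  b <- select_stimulated_neurons(c(55, 50), 2, 45, geom, exclude = a)
  expect_length(intersect(a, b), 0)

  expect_error(select_stimulated_neurons(c(5, 5), sigma = 0.01, n = 500,
                                         grid_geometry(10, 10)),
               "not enough")
})

test_that("stimulus protocol lays out an alternating non-overlapping schedule", {
  geom <- grid_geometry(50, 50)
  prot <- stimulus_protocol(geom, n_stimulated = 45, amplitude_pA = 100,
                            on_ms = 1000, pause_ms = 2000, n_trials = 20, seed = 2)
  expect_length(prot$targets_a, 45)
  expect_length(prot$targets_b, 45)
  expect_length(intersect(prot$targets_a, prot$targets_b), 0)
  expect_equal(prot$onsets_b - prot$onsets_a, rep(3000, 20))
  expect_equal(diff(prot$onsets_a), rep(6000, 19))
  expect_equal(prot$total_ms, 120000)
  # reproducible selection
  prot2 <- stimulus_protocol(geom, n_stimulated = 45, seed = 2)
  expect_identical(prot2$targets_a, prot$targets_a)
})

test_that("synthetic fixtures carry their stated ground truth", {
  # planted bumps: the detector recovers all five centroids within 1 grid unit
  fx <- generate_fixture("planted_bumps", seed = 1)
  truth <- attr(fx, "ground_truth")$centers
  rk <- build_ricker(3)
  bs <- detect_bumps_frames(fx, rk)
  for (b in bs) {
    expect_identical(nrow(b), length(truth))
    for (ct in truth) {
      expect_lt(min(torus_distance(b$cx, b$cy, ct[1], ct[2], fx$geometry)), 1)
    }
  }

  # poisson raster: rates recovered within 0.5 spikes/s at 100 s
  ras <- generate_fixture("poisson_raster",
                          params = list(n_neurons = 50, rate = 10,
                                        duration_ms = 1e5), seed = 2)
  rs <- firing_rates(ras)
  expect_lt(abs(rs$mean - 10), 0.5)

  # periodic train: CV exactly zero
  per <- generate_fixture("periodic_train", params = list(rate = 20), seed = 3)
  expect_equal(cv_isi(per$spikes$time_ms), 0)

  expect_error(generate_fixture("nonsense"), "arg")
  # deterministic given seed
  expect_identical(generate_fixture("poisson_raster", seed = 9)$spikes,
                   generate_fixture("poisson_raster", seed = 9)$spikes)
})

test_that("two-stimulus protocol: zero amplitude gives unit delta-response, stimulation raises it monotonically with FF peaking at onset", {
  p <- reduced_preset("gamma")
  net <- reduced_gamma_net()
  drive <- p$drive_grid[2] # transition regime: nonzero background rate
  meds <- c()
  for (amp in c(0, 50, 150)) {
    prot <- stimulus_protocol(p$geometry, n_stimulated = 45, amplitude_pA = amp,
                              on_ms = 500, pause_ms = 1000, n_trials = 6, seed = 3)
    pr <- run_two_stimulus_protocol(net, prot, drive = drive, seed = 21)
    expect_identical(nrow(pr$responses), 12L)
    med <- stats::median(pr$responses$delta_response, na.rm = TRUE)
    meds <- c(meds, med)
    if (amp == 0) {
      expect_lt(abs(med - 1), 0.35)
    } else if (amp == 150) {
      # a strong stimulus: trial-to-trial variability transient at onset,
      # then a reliable (low-FF) steady response
      ff_on <- subset(pr$fano, time_ms < 100)$fano
      ff_steady <- subset(pr$fano, time_ms >= 200 & time_ms < 500)$fano
      expect_gt(mean(ff_on, na.rm = TRUE), mean(ff_steady, na.rm = TRUE))
    }
  }
  expect_true(all(diff(meds) > 0),
              label = "median delta-response increases with amplitude 0 -> 50 -> 150 pA")
})

test_that("the full pipeline is deterministic given config and seeds", {
  p <- reduced_preset("gamma")
  net <- build_network(grid_geometry(20, 20), kernel_spec("gamma", 8, 0.5),
                       k = 40, seed = 5)
  run <- function() {
    res <- simulate_network(net, drive = 2500, duration_ms = 1000, seed = 31)
    list(rates = firing_rates(res)$rates,
         cv = cv_isi_per_neuron(res),
         frames = make_frames(res)$frames)
  }
  a <- run()
  b <- run()
  expect_identical(a, b)
})

test_that("run_sweep summarises points and survives failing ones", {
  sw <- run_sweep(values = c(500, 2500), variable = "nu_ext",
                  preset = list(geometry = grid_geometry(20, 20),
                                kernel = kernel_spec("gamma", 8, 0.5),
                                k = 40L),
                  duration_ms = 1000, seed = 2)
  expect_identical(nrow(sw), 2L)
  expect_true(all(is.na(sw$error)))
  expect_lt(sw$mean_rate[1], sw$mean_rate[2])
  # 1 s of activity is below the classification minimum: state stays NA
  expect_true(all(is.na(sw$state)))

  bad <- run_sweep(values = list(kernel_spec("gamma", 8, 0.5),
                                 kernel_spec("gaussian", sigma = 1e-9)),
                   variable = "kernel",
                   preset = list(geometry = grid_geometry(20, 20), k = 20L),
                   duration_ms = 500, seed = 3, nu_ext = 2000)
  expect_true(is.na(bad$error[1]))
  expect_match(bad$error[2], "converge")
})
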