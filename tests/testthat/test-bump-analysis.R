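test_that("make_frames bins spikes into the right windows and conserves counts", {
  geom <- grid_geometry(10, 10)
  empty <- tibble::tibble(neuron = integer(0), time_ms = numeric(0))
  fr0 <- make_frames(empty, geom, window_ms = 100, duration_ms = 1000)
  expect_length(fr0$frames, 10)
  expect_true(all(vapply(fr0$frames, sum, numeric(1)) == 0))

  one <- tibble::tibble(neuron = idx_from_xy(3, 7, geom), time_ms = 150)
  fr1 <- make_frames(one, geom, window_ms = 100, duration_ms = 1000)
  expect_equal(sum(fr1$frames[[2]]), 1)
  expect_equal(fr1$frames[[2]][4, 8], 1) # matrix is [x + 1, y + 1]
  expect_equal(sum(vapply(fr1$frames, sum, numeric(1))), 1)

  res <- simulate_network(tiny_net(), drive = 3000, duration_ms = 10000, seed = 2)
  fr <- make_frames(res)
  expect_length(fr$frames, 100)
  expect_equal(sum(vapply(fr$frames, sum, numeric(1))), nrow(res$spikes))
  frb <- make_frames(res, binary = TRUE)
  expect_true(all(vapply(frb$frames, max, numeric(1)) <= 1))
})

test_that("Ricker kernel satisfies the zero/±1 integral normalisation and symmetry", {
  for (w in c(1, 1.6, 3.2)) {
    rk <- build_ricker(w)
    expect_lt(abs(sum(rk)), 1e-9)
    expect_equal(sum(rk[rk > 0]), 1, tolerance = 1e-12)
    expect_equal(sum(rk[rk < 0]), -1, tolerance = 1e-12)
    expect_equal(unclass(rk), unclass(rk)[rev(seq_len(nrow(rk))), rev(seq_len(ncol(rk)))],
                 ignore_attr = TRUE)
  }
  expect_error(build_ricker(2, support = 4), "at least 3")
})

test_that("a spatially uniform frame filters to exactly zero (no bumps)", {
  rk <- build_ricker(1.6)
  for (level in c(0, 3, 17)) {
    frame <- matrix(level, 50, 50)
    filt <- striatnet:::torus_convolve(frame, rk)
    expect_lt(max(abs(filt)), 1e-6)
    bs <- detect_bumps(frame, rk, threshold = 0.5)
    expect_identical(nrow(bs), 0L)
  }
})

test_that("planted Gaussian blobs are recovered at their true centroids", {
  geom <- grid_geometry(100, 100)
  rk <- build_ricker(3)
  blob_frame <- function(centers, sigma = 3, peak = 8) {
    xy <- xy_from_idx(0:(geom$n - 1), geom)
    lam <- rep(0, geom$n)
    for (ct in centers) {
      d <- torus_distance(xy$x, xy$y, ct[1], ct[2], geom)
      lam <- lam + peak * exp(-d^2 / (2 * sigma^2))
    }
    matrix(lam, 100, 100, byrow = TRUE)
  }
  # one blob (deterministic intensity, no noise)
  b1 <- detect_bumps(blob_frame(list(c(30, 70))), rk)
  expect_identical(nrow(b1), 1L)
  expect_lt(torus_distance(b1$cx, b1$cy, 30, 70, geom), 1)

  # two blobs well apart
  b2 <- detect_bumps(blob_frame(list(c(20, 20), c(20, 40))), rk)
  expect_identical(nrow(b2), 2L)

  # blob across the torus seam is still one bump with a wrapped centroid
  b3 <- detect_bumps(blob_frame(list(c(0, 99))), rk)
  expect_identical(nrow(b3), 1L)
  expect_lt(torus_distance(b3$cx, b3$cy, 0, 99, geom), 1)
})

test_that("detection is translation-equivariant on the torus", {
  fx <- generate_fixture("planted_bumps",
                         params = list(n_frames = 1, noise = 0.05), seed = 3)
  frame <- fx$frames[[1]]
  rk <- build_ricker(3)
  base <- detect_bumps(frame, rk)
  sh <- c(17, 62)
  shifted <- frame[((0:99 - sh[1]) %% 100) + 1, ((0:99 - sh[2]) %% 100) + 1]
  moved <- detect_bumps(shifted, rk)
  expect_identical(nrow(moved), nrow(base))
  # every shifted centroid matches a base centroid + shift (mod 100)
  for (i in seq_len(nrow(base))) {
    d <- torus_distance(moved$cx, moved$cy,
                        (base$cx[i] + sh[1]) %% 100, (base$cy[i] + sh[2]) %% 100,
                        fx$geometry)
    expect_lt(min(d), 0.35)
  }
})

test_that("count and binary frames agree on bump counts for well-formed bumps", {
  fx <- generate_fixture("planted_bumps",
                         params = list(n_frames = 3, noise = 0.05, peak = 6),
                         seed = 8)
  rk <- build_ricker(3)
  for (f in seq_along(fx$frames)) {
    counts <- detect_bumps(fx$frames[[f]], rk)
    binar <- detect_bumps((fx$frames[[f]] > 0) * 1, rk)
    expect_identical(nrow(counts), nrow(binar))
  }
})

test_that("greedy nearest-neighbour tracking produces the expected track structure", {
  geom <- grid_geometry(50, 50)
  mk <- function(cx, cy) {
    out <- tibble::tibble(bump = seq_along(cx), cx = cx, cy = cy,
                          n_pixels = 5L, peak_activity = 1,
                          members = vector("list", length(cx)))
    out
  }
  # one fixed bump over 8 frames: a single full-length track
  sets <- replicate(8, mk(10, 10), simplify = FALSE)
  tr <- track_bumps(sets, geom, link_radius = 3, window_ms = 100)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$lifespan, 8L)
  expect_equal(tr$lifespan_norm, 1)

  # a bump present in one frame only
  sets1 <- list(mk(numeric(0), numeric(0)), mk(5, 5), mk(numeric(0), numeric(0)))
  tr1 <- track_bumps(sets1, geom, link_radius = 3, window_ms = 100)
  expect_identical(tr1$lifespan, 1L)

  # two sites 20 apart, alternating occupancy, link radius 5:
  # no links possible, one new track per appearance
  alt <- lapply(1:6, function(f) if (f %% 2 == 1) mk(10, 10) else mk(10, 30))
  tra <- track_bumps(alt, geom, link_radius = 5, window_ms = 100)
  expect_identical(nrow(tra), 6L)
  expect_true(all(tra$lifespan == 1L))

  # two simultaneous bumps moving slowly: two parallel tracks
  two <- lapply(0:5, function(f) mk(c(10 + 0.3 * f, 40), c(10, 5 + 0.3 * f)))
  trt <- track_bumps(two, geom, link_radius = 2, window_ms = 100)
  expect_identical(nrow(trt), 2L)
  expect_true(all(trt$lifespan == 6L))

  # track structure is invariant to bump order within frames
  twor <- lapply(two, function(s) s[rev(seq_len(nrow(s))), ])
  trr <- track_bumps(twor, geom, link_radius = 2, window_ms = 100)
  expect_identical(sort(trr$lifespan), sort(trt$lifespan))
})

test_that("bump summaries report counts, spacing and lifespan bands correctly", {
  geom <- grid_geometry(60, 60)
  # synthetic hexagonal-ish lattice of blobs with spacing 15
  centers <- list()
  for (i in 0:3) for (j in 0:3) {
    centers[[length(centers) + 1]] <- c((i * 15 + (j %% 2) * 7.5) %% 60, (j * 15) %% 60)
  }
  xy <- xy_from_idx(0:(geom$n - 1), geom)
  lam <- rep(0.05, geom$n)
  for (ct in centers) {
    d <- torus_distance(xy$x, xy$y, ct[1], ct[2], geom)
    lam <- lam + 8 * exp(-d^2 / (2 * 2^2))
  }
  set.seed(4)
  frames <- lapply(1:6, function(f)
    matrix(stats::rpois(geom$n, lam), 60, 60, byrow = TRUE))
  fr <- structure(list(frames = frames, window_ms = 100, duration_ms = 600,
                       geometry = geom), class = "activity_frames")
  rk <- build_ricker(2.5)
  bs <- detect_bumps_frames(fr, rk)
  tr <- track_bumps(bs, geom, link_radius = 3, window_ms = 100)
  sm <- bump_summary(tr, bs, geom)
  expect_equal(sm$count_mean, 16, tolerance = 0.05)
  expect_lt(abs(sm$median_spacing - 15), 1.0)
  expect_true(sm$spacing_defined)
  expect_identical(sum(sm$lifespan_bands$n), nrow(tr))

  # single persistent bump: count 1 +/- 0, spacing flagged undefined
  one <- replicate(6, detect_bumps(frames[[1]] * 0 +
    matrix(stats::rpois(geom$n, 8 * exp(-torus_distance(xy$x, xy$y, 30, 30, geom)^2 / 8)),
           60, 60, byrow = TRUE), rk), simplify = FALSE)
  tro <- track_bumps(one, geom, link_radius = 3, window_ms = 100)
  smo <- bump_summary(tro, one, geom)
  expect_equal(smo$count_mean, 1)
  expect_identical(smo$count_sd, 0)
  expect_false(smo$spacing_defined)
})

test_that("detection conclusions are robust over threshold multipliers 4-6", {
  fx <- generate_fixture("planted_bumps",
                         params = list(n_frames = 2, noise = 0.1), seed = 5)
  rk <- build_ricker(3)
  for (z in c(4, 5, 6)) {
    for (f in seq_along(fx$frames)) {
      bs <- detect_bumps(fx$frames[[f]], rk, threshold_sd = z)
      expect_identical(nrow(bs), 5L)
    }
  }
})
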