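#' Network presets
#'
#' `full_preset()` is the reference architecture: 100 x 100 torus, out-degree
#' 1000 (10% connection probability), gamma kernel with shape 24 and scale
#' 0.4 grid units (connection-distance mode at 9.2 grid units = 92 um, near
#' the ~80 um peak reported for striatal medium spiny neuron pairs, decaying
#' to zero well before 200 um) or Gaussian kernel with sigma 8. The ring
#' must be this sharp for the bump instability to clear its threshold in a
#' 2D network: the radial (Hankel) transform of a 2D wiring profile dips far
#' less deeply than the 1D transform of the same gamma density, so broad
#' rings (small shape n) never destabilise the homogeneous state at
#' realistic synaptic strengths. `reduced_preset()` scales everything down
#' for fast analysis: 50 x 50 grid, out-degree 250, kernel scales halved
#' (gamma theta 0.2, Gaussian sigma 4). The qualitative state repertoire
#' (AI / TA / WTA for gamma, AI-only for Gaussian) is preserved at the
#' reduced scale; the drive values that bracket the three regimes there are
#' recorded in `drive_grid` (the AI band of the reduced network sits at
#' lower drives and rates than at full scale).
#'
#' @param kind `"gamma"` or `"gaussian"`.
#' @return A list with `geometry`, `kernel`, `k`, and `drive_grid`
#'   (spikes/s values spanning AI to WTA for the gamma network).
#' @export
full_preset <- function(kind = c("gamma", "gaussian")) {
  kind <- match.arg(kind)
  list(
    geometry = grid_geometry(100, 100),
    kernel = if (kind == "gamma") kernel_spec("gamma", n = 24, theta = 0.4)
             else kernel_spec("gaussian", sigma = 8),
    k = 1000L,
    drive_grid = c(1000, 1500, 3000)
  )
}

#' @rdname full_preset
#' @export
reduced_preset <- function(kind = c("gamma", "gaussian")) {
  kind <- match.arg(kind)
  list(
    geometry = grid_geometry(50, 50),
    kernel = if (kind == "gamma") kernel_spec("gamma", n = 24, theta = 0.2)
             else kernel_spec("gaussian", sigma = 4),
    k = 250L,
    drive_grid = c(600, 1200, 3000)
  )
}

#' Select stimulated neurons around a centre
#'
#' Samples `n` distinct neurons without replacement with probability
#' proportional to a 2D Gaussian (width `sigma`) of the torus distance to
#' `center`. Mirrors the stimulus targeting used in the two-stimulus
#' protocol: ~45 neurons per stimulus, sigma = 2 grid points.
#'
#' @param center Length-2 vector `(x, y)` of the centre, grid coordinates.
#' @param sigma Gaussian width, grid units.
#' @param n Number of neurons to select.
#' @param geometry A [grid_geometry()].
#' @param exclude Zero-based neuron indices that must not be selected
#'   (enforces nonoverlap between the two stimulus sets).
#' @return Integer vector of `n` distinct zero-based neuron indices.
#' @export
select_stimulated_neurons <- function(center, sigma = 2, n = 45,
                                      geometry = grid_geometry(),
                                      exclude = integer(0)) {
  xy <- xy_from_idx(0:(geometry$n - 1), geometry)
  d <- torus_distance(xy$x, xy$y, center[1], center[2], geometry)
  w <- exp(-d^2 / (2 * sigma^2))
  w[xy$idx %in% exclude] <- 0
  if (sum(w > 0) < n) stop("not enough available neurons for the requested selection")
  sample(xy$idx, n, replace = FALSE, prob = w)
}

#' Two-stimulus protocol specification
#'
#' Two nonoverlapping subsets of neurons (default 45 each), centred 10 grid
#' points apart inside a 30 x 30 region of interest, stimulated alternately
#' by DC injection: each presentation lasts 1 s, separated by a 2 s pause,
#' repeated over trials.
#'
#' @param geometry A [grid_geometry()].
#' @param roi_origin Zero-based `(x, y)` of the ROI corner; default centres
#'   the 30 x 30 ROI on the grid.
#' @param centers List of two `(x, y)` stimulus centres; default symmetric
#'   about the ROI centre, 10 grid points apart.
#' @param n_stimulated Neurons per stimulus.
#' @param placement_sigma Gaussian placement width, grid units.
#' @param amplitude_pA Stimulus current, pA.
#' @param on_ms Presentation duration, ms.
#' @param pause_ms Pause between presentations, ms.
#' @param n_trials Presentations per stimulus.
#' @param seed Seed for neuron selection.
#' @return A list of class `stimulus_protocol` including the selected index
#'   sets `targets_a`, `targets_b` and the presentation schedule.
#' @export
stimulus_protocol <- function(geometry = grid_geometry(),
                              roi_origin = NULL, centers = NULL,
                              n_stimulated = 45, placement_sigma = 2,
                              amplitude_pA = 100, on_ms = 1000,
                              pause_ms = 2000, n_trials = 20, seed = 1L) {
  roi_origin <- roi_origin %||% c((geometry$nrow - 30) %/% 2, (geometry$ncol - 30) %/% 2)
  roi_center <- roi_origin + 15
  centers <- centers %||% list(roi_center + c(-5, 0), roi_center + c(5, 0))
  stopifnot(length(centers) == 2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  a <- select_stimulated_neurons(centers[[1]], placement_sigma, n_stimulated, geometry)
  b <- select_stimulated_neurons(centers[[2]], placement_sigma, n_stimulated, geometry,
                                 exclude = a)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  # alternating schedule: A, pause, B, pause, A, ...
  onsets_a <- (seq_len(n_trials) - 1) * 2 * (on_ms + pause_ms)
  onsets_b <- onsets_a + on_ms + pause_ms
  structure(list(
    geometry = geometry, roi_origin = roi_origin, centers = centers,
    targets_a = sort(a), targets_b = sort(b),
    n_stimulated = n_stimulated, placement_sigma = placement_sigma,
    amplitude_pA = amplitude_pA, on_ms = on_ms, pause_ms = pause_ms,
    n_trials = n_trials,
    onsets_a = onsets_a, onsets_b = onsets_b,
    total_ms = n_trials * 2 * (on_ms + pause_ms)
  ), class = "stimulus_protocol")
}

#' Run the alternating two-stimulus protocol
#'
#' Simulates the network once for the whole protocol (both stimuli
#' interleaved on their schedule) and computes per-presentation
#' `delta_response` (evoked over the 1 s pre-onset background, per stimulus
#' set), the across-presentation Fano factor time series in 100 ms windows
#' aligned to onset, and correlation spectra of the stimulated neurons for
#' ongoing vs evoked epochs.
#'
#' @param table A `connectivity_table`.
#' @param protocol A [stimulus_protocol()].
#' @param drive A [background_drive()] or rate in spikes/s.
#' @param seed Simulation seed.
#' @param synapse Optional [synapse_parameters()].
#' @return A list of class `protocol_result`: `result` (the `sim_result`),
#'   `responses` (tibble: stimulus, presentation, evoked/background rates,
#'   `delta_response`), `fano` (tibble per stimulus), `correlations`
#'   (list: ongoing / evoked `correlation_spectrum`).
#' @export
run_two_stimulus_protocol <- function(table, protocol, drive, seed = 1L,
                                      synapse = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  neuron <- neuron_parameters()
  synapse <- synapse %||% calibrated_synapses(neuron)
  stim <- c(
    lapply(protocol$onsets_a, function(t0)
      stimulus_spec(protocol$targets_a, protocol$amplitude_pA, t0, t0 + protocol$on_ms)),
    lapply(protocol$onsets_b, function(t0)
      stimulus_spec(protocol$targets_b, protocol$amplitude_pA, t0, t0 + protocol$on_ms))
  )
  res <- simulate_network(table, neuron, synapse, drive, stim,
                          duration_ms = protocol$total_ms, seed = seed)

  rate_in <- function(targets, from, to) {
    sel <- res$spikes$neuron %in% targets &
      res$spikes$time_ms > from & res$spikes$time_ms <= to
    sum(sel) / length(targets) / ((to - from) / 1000)
  }
  resp <- dplyr::bind_rows(lapply(c("A", "B"), function(lab) {
    onsets <- if (lab == "A") protocol$onsets_a else protocol$onsets_b
    targets <- if (lab == "A") protocol$targets_a else protocol$targets_b
    dplyr::bind_rows(lapply(seq_along(onsets), function(i) {
      t0 <- onsets[i]
      bg_from <- max(0, t0 - 1000)
      bg <- if (t0 > 0) rate_in(targets, bg_from, t0) else NA_real_
      ev <- rate_in(targets, t0, t0 + protocol$on_ms)
      tibble::tibble(stimulus = lab, presentation = i,
                     background_rate = bg, evoked_rate = ev,
                     delta_response = delta_response(ev, bg))
    }))
  }))

  fano_win <- 100
  nwin <- floor((protocol$on_ms + protocol$pause_ms) / fano_win)
  fano <- dplyr::bind_rows(lapply(c("A", "B"), function(lab) {
    onsets <- if (lab == "A") protocol$onsets_a else protocol$onsets_b
    targets <- if (lab == "A") protocol$targets_a else protocol$targets_b
    counts <- t(vapply(onsets, function(t0) {
      vapply(seq_len(nwin), function(w) {
        sum(res$spikes$neuron %in% targets &
              res$spikes$time_ms > t0 + (w - 1) * fano_win &
              res$spikes$time_ms <= t0 + w * fano_win)
      }, numeric(1))
    }, numeric(nwin)))
    ff <- fano_factor(counts)
    ff$stimulus <- lab
    ff$time_ms <- ff$window * fano_win
    ff
  }))

  roi_neurons <- roi_indices(protocol)
  both <- sort(c(protocol$targets_a, protocol$targets_b))
  corr <- list(
    evoked = correlation_spectrum(res, neurons = both, bin_ms = 100),
    roi = correlation_spectrum(res, neurons = roi_neurons, bin_ms = 100)
  )
  structure(list(result = res, responses = resp, fano = fano,
                 correlations = corr, protocol = protocol),
            class = "protocol_result")
}

# zero-based indices of the 30x30 ROI
roi_indices <- function(protocol) {
  g <- protocol$geometry
  ox <- protocol$roi_origin[1]
  oy <- protocol$roi_origin[2]
  grid <- expand.grid(x = ox:(ox + 29), y = oy:(oy + 29))
  sort(idx_from_xy(grid$x, grid$y, g))
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  print(dplyr::summarise(dplyr::group_by(x$responses, .data$stimulus),
                         median_delta = stats::median(.data$delta_response, na.rm = TRUE),
                         .groups = "drop"))
  invisible(x)
}

#' End-to-end bump analysis of a simulation
#'
#' Convenience pipeline: frames -> Ricker filtering and detection ->
#' tracking -> summary and state label. The Ricker width defaults to the
#' field-theory scale `1 / k_c` of the network's kernel (the predicted bump
#' spacing over 2 pi) when the kernel admits one, else 3 grid units.
#'
#' @param result A `sim_result` from a wired network.
#' @param width Ricker width override, grid units.
#' @param threshold_sd Detection threshold in per-frame sd units.
#' @param link_radius Tracking radius override, grid units (default one
#'   kernel width).
#' @param window_ms Frame length, ms.
#' @param binary Detect on binarised (any-spike) frames, the reference
#'   method; `FALSE` uses raw spike counts, which lets single bursting
#'   neurons masquerade as spatial bumps in strongly driven networks.
#' @param kernel_spec_override Kernel used for the width default.
#' @return A list of class `bump_analysis`: `frames`, `bumpsets`, `tracks`,
#'   `summary`, `state` (tibble from [classify_state()], `NULL` if run is
#'   shorter than the classification minimum).
#' @export
analyze_bumps <- function(result, width = NULL, threshold_sd = 5,
                          link_radius = NULL, window_ms = 100, binary = TRUE,
                          kernel_spec_override = NULL) {
  stopifnot(inherits(result, "sim_result"), !is.null(result$geometry))
  ker <- kernel_spec_override %||% result$kernel
  if (is.null(width)) {
    kc <- if (is.null(ker)) NA_real_ else
      tryCatch(critical_wavenumber(ker), error = function(e) NA_real_)
    width <- if (is.na(kc)) 3 else 1 / kc
  }
  rk <- build_ricker(width)
  frames <- make_frames(result, window_ms = window_ms, binary = binary)
  bumpsets <- detect_bumps_frames(frames, rk, threshold_sd = threshold_sd)
  tracks <- track_bumps(bumpsets, result$geometry,
                        link_radius = link_radius %||% width,
                        window_ms = window_ms,
                        duration_ms = result$duration_ms)
  state <- tryCatch(classify_state(tracks, bumpsets), error = function(e) NULL)
  structure(list(frames = frames, bumpsets = bumpsets, tracks = tracks,
                 summary = bump_summary(tracks, bumpsets, result$geometry,
                                        result = result),
                 state = state, width = width),
            class = "bump_analysis")
}

#' @export
print.bump_analysis <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$state)) {
    cat(sprintf("  state: %s\n", as.character(x$state$state)))
  }
  invisible(x)
}

#' Sweep a parameter and summarise each point
#'
#' Runs one simulation per sweep point — over the background drive
#' (`variable = "nu_ext"`) or the gamma-kernel parameters
#' (`variable = "kernel"`, values as a list of [kernel_spec()]) — and
#' collects rate statistics, bump statistics, the state label and, for
#' kernel sweeps, the field-theory spacing prediction. Failed points are
#' recorded and the sweep continues.
#'
#' @param values Sweep values: numeric drive rates, or a list of
#'   `kernel_spec`s.
#' @param variable `"nu_ext"` or `"kernel"`.
#' @param preset Base configuration from [reduced_preset()] /
#'   [full_preset()].
#' @param duration_ms Simulated time per point.
#' @param seed Base seed; point `i` uses `seed + i - 1` for wiring and
#'   simulation.
#' @param nu_ext Fixed drive for kernel sweeps, spikes/s.
#' @param threshold_sd Bump-detection threshold.
#' @return A tibble with one row per point: the swept value, `mean_rate`,
#'   `sd_rate`, `skewness`, `mean_count`, `median_lifespan_norm`, `state`,
#'   `median_spacing`, `predicted_spacing`, `error` (message or `NA`).
#' @export
run_sweep <- function(values, variable = c("nu_ext", "kernel"),
                      preset = reduced_preset("gamma"), duration_ms = 5000,
                      seed = 1L, nu_ext = 5000, threshold_sd = 2) {
  variable <- match.arg(variable)
  stopifnot(length(values) >= 2)
  rows <- lapply(seq_along(values), function(i) {
    pt_seed <- seed + i - 1L
    out <- tibble::tibble(
      point = i, nu_ext = NA_real_, kernel_n = NA_real_, kernel_theta = NA_real_,
      mean_rate = NA_real_, sd_rate = NA_real_, skewness = NA_real_,
      mean_count = NA_real_, median_lifespan_norm = NA_real_,
      state = factor(NA, levels = c("AI", "TA", "WTA")),
      median_spacing = NA_real_, predicted_spacing = NA_real_,
      error = NA_character_)
    tryCatch({
      if (variable == "nu_ext") {
        kernel <- preset$kernel
        drive <- values[[i]]
      } else {
        kernel <- values[[i]]
        drive <- nu_ext
      }
      out$nu_ext <- drive
      if (kernel$kind == "gamma") {
        out$kernel_n <- kernel$n
        out$kernel_theta <- kernel$theta
      }
      net <- build_network(preset$geometry, kernel, preset$k,
                           seed = derive_seed(pt_seed, "wiring"))
      res <- simulate_network(net, drive = drive, duration_ms = duration_ms,
                              seed = pt_seed)
      rs <- firing_rates(res)
      ba <- analyze_bumps(res, threshold_sd = threshold_sd,
                          kernel_spec_override = kernel)
      out$mean_rate <- rs$mean
      out$sd_rate <- rs$sd
      out$skewness <- rs$skewness
      out$mean_count <- ba$summary$count_mean
      out$median_lifespan_norm <- if (nrow(ba$tracks) > 0)
        stats::median(ba$tracks$lifespan_norm) else 0
      if (!is.null(ba$state)) out$state <- ba$state$state
      out$median_spacing <- ba$summary$median_spacing
      out$predicted_spacing <- tryCatch(predict_bump_spacing(kernel),
                                        error = function(e) NA_real_)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  dplyr::bind_rows(rows)
}

#' Synthetic fixtures with known ground truth
#'
#' Deterministic (seeded) synthetic data for testing the analysis pipeline:
#' * `"poisson_raster"`: independent Poisson spike trains
#'   (`params$n_neurons`, `params$rate`, `params$duration_ms`) as a
#'   `sim_result`-shaped object; ground-truth rate and CV are known.
#' * `"planted_bumps"`: activity frames with Gaussian blobs of rate
#'   `params$peak` planted at `params$centers` (list of `(x, y)`), width
#'   `params$blob_sigma`, on Poisson background noise `params$noise`;
#'   ground truth is the centroid list.
#' * `"periodic_train"`: a single perfectly periodic train
#'   (`params$rate`, `params$duration_ms`), CV exactly 0.
#'
#' @param kind Fixture kind.
#' @param params Named list of parameters (see above; all have defaults).
#' @param seed Integer seed.
#' @return A `sim_result` (rasters/trains) or `activity_frames`
#'   (planted bumps) with a `ground_truth` attribute.
#' @export
generate_fixture <- function(kind = c("poisson_raster", "planted_bumps",
                                      "periodic_train"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  p <- params
  if (kind == "poisson_raster") {
    n <- p$n_neurons %||% 100L
    rate <- p$rate %||% 10
    dur <- p$duration_ms %||% 10000
    trains <- lapply(seq_len(n) - 1L, function(i) {
      t <- poisson_input_stream(rate, dur)
      tibble::tibble(neuron = rep(i, length(t)), time_ms = t)
    })
    res <- fixture_result(dplyr::bind_rows(trains), n, dur)
    attr(res, "ground_truth") <- list(rate = rate, cv = 1)
    res
  } else if (kind == "periodic_train") {
    rate <- p$rate %||% 10
    dur <- p$duration_ms %||% 10000
    t <- seq(1000 / rate, dur, by = 1000 / rate)
    res <- fixture_result(tibble::tibble(neuron = rep(0L, length(t)), time_ms = t),
                          1L, dur)
    attr(res, "ground_truth") <- list(rate = rate, cv = 0)
    res
  } else {
    geom <- p$geometry %||% grid_geometry(100, 100)
    centers <- p$centers %||% list(c(20, 20), c(20, 70), c(60, 30),
                                   c(70, 75), c(45, 50))
    blob_sigma <- p$blob_sigma %||% 3
    peak <- p$peak %||% 8
    noise <- p$noise %||% 0.1
    n_frames <- p$n_frames %||% 5
    xy <- xy_from_idx(0:(geom$n - 1), geom)
    lam <- rep(noise, geom$n)
    for (ct in centers) {
      d <- torus_distance(xy$x, xy$y, ct[1], ct[2], geom)
      lam <- lam + peak * exp(-d^2 / (2 * blob_sigma^2))
    }
    frames <- lapply(seq_len(n_frames), function(f) {
      counts <- stats::rpois(geom$n, lam)
      matrix(counts, nrow = geom$nrow, ncol = geom$ncol, byrow = TRUE)
    })
    out <- structure(list(frames = frames, window_ms = 100,
                          duration_ms = n_frames * 100, geometry = geom),
                     class = "activity_frames")
    attr(out, "ground_truth") <- list(centers = centers, blob_sigma = blob_sigma)
    out
  }
}

# minimal sim_result wrapper for synthetic spike data
fixture_result <- function(spikes, n_neurons, duration_ms) {
  structure(list(spikes = spikes, n_neurons = as.integer(n_neurons),
                 duration_ms = duration_ms, dt = NA_real_, seed = NA_integer_,
                 geometry = NULL,
                 neuron_parameters = NULL, synapse_parameters = NULL,
                 drive = background_drive(0), stimuli = NULL),
            class = "sim_result")
}
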