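#' @useDynLib striatnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Background excitatory drive
#'
#' Uncorrelated homogeneous Poisson spike trains, one independent realization
#' per neuron, delivered through the excitatory alpha synapse. The rate
#' `nu_ext` (spikes/s per neuron) is the main control parameter of the
#' network: increasing it moves a gamma-kernel network through the
#' asynchronous-irregular (AI), transition (TA) and winner-take-all (WTA)
#' regimes.
#'
#' @param nu_ext Poisson rate per neuron, spikes/s (`>= 0`).
#' @return A list of class `background_drive`.
#' @export
background_drive <- function(nu_ext) {
  stopifnot(nu_ext >= 0)
  structure(list(nu_ext = nu_ext, independent = TRUE),
            class = "background_drive")
}

#' Direct-current stimulus specification
#'
#' A constant current injected into a set of target neurons between `onset`
#' and `offset`.
#'
#' @param targets Zero-based neuron indices receiving the current.
#' @param amplitude_pA Current amplitude, pA.
#' @param onset_ms,offset_ms Stimulus window, ms (`offset > onset`).
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(targets, amplitude_pA, onset_ms, offset_ms) {
  stopifnot(offset_ms > onset_ms, all(targets >= 0))
  structure(list(targets = as.integer(targets),
                 amplitude_pA = amplitude_pA,
                 onset_ms = onset_ms, offset_ms = offset_ms),
            class = "stimulus_spec")
}

derive_seed <- function(seed, stream) {
  offset <- c(wiring = 11L, background = 127L, init = 509L)[[stream]]
  as.integer((as.double(seed) * 69069 + offset) %% 2147483647)
}

#' Simulate the inhibitory spiking network
#'
#' Integrates the conductance-based LIF network at a fixed step `dt`
#' (default 0.1 ms):
#' `C_m dv/dt = -g_L (v - E_L) - g_exc(t)(v - E_exc) - g_inh(t)(v - E_inh) + I_DC(t)`.
#' Threshold crossings emit a spike at the end of the step, reset the neuron
#' and clamp it for the refractory period; recurrent spikes reach their
#' targets after the synaptic delay as inhibitory alpha conductances;
#' background Poisson events arrive as excitatory alpha conductances.
#'
#' Randomness is split over two named streams derived from `seed`: initial
#' membrane potentials (drawn uniformly in `[V_reset, V_th]`) and the
#' background Poisson input. Either can be frozen via `init_seed` /
#' `background_seed`. Identical arguments give identical results.
#'
#' @param table A `connectivity_table` from [build_network()], or `NULL` for
#'   unconnected neurons (single-neuron protocols).
#' @param neuron A [neuron_parameters()].
#' @param synapse A [synapse_parameters()]; `NA` peak conductances are
#'   calibrated with [calibrate_psp()] to the reference unitary amplitudes.
#' @param drive A [background_drive()] or a plain rate in spikes/s.
#' @param stimuli A list of [stimulus_spec()] (or a single one, or `NULL`).
#' @param duration_ms Simulated time, ms.
#' @param seed Master seed (integer).
#' @param dt Integration step, ms.
#' @param n_neurons Number of neurons when `table` is `NULL`.
#' @param init_seed,background_seed Optional explicit stream seeds.
#' @param v_init Optional vector of initial membrane potentials, mV.
#' @param record_neuron Optional zero-based index of one neuron whose voltage
#'   trajectory is recorded.
#' @return An object of class `sim_result`: list with `spikes` (tibble
#'   `neuron` zero-based, `time_ms`), `n_neurons`, `duration_ms`, `dt`,
#'   `seed`, the parameter blocks, the geometry (if wired) and optionally
#'   `v_trace`.
#' @examples
#' net <- build_network(grid_geometry(10, 10), kernel_spec("gamma", 3, 1.5),
#'                      k = 20, seed = 1)
#' res <- simulate_network(net, drive = 2000, duration_ms = 200, seed = 1)
#' glance(res)
#' @export
simulate_network <- function(table = NULL,
                             neuron = neuron_parameters(),
                             synapse = calibrated_synapses(neuron),
                             drive = background_drive(0),
                             stimuli = NULL,
                             duration_ms = 1000, seed = 1L, dt = 0.1,
                             n_neurons = NULL,
                             init_seed = NULL, background_seed = NULL,
                             v_init = NULL, record_neuron = NULL) {
  stopifnot(duration_ms > 0, dt > 0)
  if (is.numeric(drive)) drive <- background_drive(drive)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (synapse$delay < dt) stop("synaptic delay must be at least one integration step")
  if (is.null(table)) {
    n <- as.integer(n_neurons %||% 1L)
    targets <- matrix(integer(0), nrow = 0, ncol = n)
    geometry <- NULL
  } else {
    stopifnot(inherits(table, "connectivity_table"))
    n <- table$geometry$n
    targets <- table$targets
    geometry <- table$geometry
  }
  g_exc <- synapse$g_peak_exc
  g_inh <- synapse$g_peak_inh
  if (is.na(g_exc)) g_exc <- calibrate_psp("exc", synapse$tau_exc, -70, 1.6, neuron, dt)
  if (is.na(g_inh)) g_inh <- calibrate_psp("inh", synapse$tau_inh, -44, 0.8, neuron, dt)

  if (is.null(v_init)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(init_seed %||% derive_seed(seed, "init"))
    v_init <- stats::runif(n, neuron$V_reset, neuron$V_th)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  stopifnot(length(v_init) == n)

  stim_neuron <- integer(0); stim_amp <- stim_on <- stim_off <- numeric(0)
  for (st in (stimuli %||% list())) {
    stopifnot(inherits(st, "stimulus_spec"))
    if (any(st$targets >= n)) stop("stimulus targets outside the network")
    stim_neuron <- c(stim_neuron, st$targets)
    stim_amp <- c(stim_amp, rep(st$amplitude_pA, length(st$targets)))
    stim_on <- c(stim_on, rep(st$onset_ms, length(st$targets)))
    stim_off <- c(stim_off, rep(st$offset_ms, length(st$targets)))
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(background_seed %||% derive_seed(seed, "background"))
  core <- simulate_core(
    targets, n,
    neuron$C_m, neuron$g_L, neuron$E_L, neuron$V_th, neuron$V_reset,
    neuron$t_ref, neuron$E_exc, neuron$E_inh,
    synapse$tau_exc, synapse$tau_inh, g_exc, g_inh, synapse$delay,
    drive$nu_ext, v_init,
    stim_neuron, stim_amp, stim_on, stim_off,
    duration_ms, dt,
    if (is.null(record_neuron)) -1L else as.integer(record_neuron)
  )
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  res <- structure(
    list(spikes = tibble::tibble(neuron = core$neuron, time_ms = core$time_ms),
         n_neurons = n, duration_ms = duration_ms, dt = dt,
         seed = as.integer(seed), geometry = geometry,
         kernel = if (!is.null(table)) table$kernel else NULL,
         neuron_parameters = neuron,
         synapse_parameters = utils::modifyList(
           synapse, list(g_peak_exc = g_exc, g_peak_inh = g_inh)),
         drive = drive, stimuli = stimuli),
    class = "sim_result"
  )
  if (!is.null(record_neuron)) {
    res$v_trace <- tibble::tibble(time_ms = dt * seq(0, length(core$v_trace) - 1),
                                  v_mV = core$v_trace)
  }
  res
}

#' @export
print.sim_result <- function(x, ...) {
  rate <- nrow(x$spikes) / x$n_neurons / (x$duration_ms / 1000)
  cat(sprintf("<sim_result> %d neurons, %g ms at dt = %g ms: %d spikes (mean %.2f spikes/s), nu_ext = %g /s, seed %d\n",
              x$n_neurons, x$duration_ms, x$dt, nrow(x$spikes), rate,
              x$drive$nu_ext, x$seed))
  invisible(x)
}

#' Tidy spikes from a simulation
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A tibble with columns `neuron` (zero-based index) and `time_ms`.
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) x$spikes

#' One-row simulation summary
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A tibble: neurons, duration, spike count, mean population rate.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n_neurons,
    duration_ms = x$duration_ms,
    dt = x$dt,
    nu_ext = x$drive$nu_ext,
    n_spikes = nrow(x$spikes),
    mean_rate = nrow(x$spikes) / x$n_neurons / (x$duration_ms / 1000),
    seed = x$seed
  )
}

#' Homogeneous Poisson event stream
#'
#' Event times of a homogeneous Poisson process, used for background drive
#' and as a test fixture (the event count over the duration is
#' Poisson-distributed and inter-event intervals are exponential).
#'
#' @param nu_ext Rate, spikes/s.
#' @param duration_ms Duration, ms.
#' @return Sorted numeric vector of event times in ms.
#' @export
poisson_input_stream <- function(nu_ext, duration_ms) {
  stopifnot(nu_ext >= 0, duration_ms > 0)
  n <- stats::rpois(1, nu_ext * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}

#' Write / read spikes as plain text
#'
#' Two-column tab-separated table (`neuron`, `time_ms`) with `#` header lines
#' carrying run metadata, readable back into a spikes tibble.
#'
#' @param result A `sim_result` (or a spikes tibble plus `duration_ms`).
#' @param path File path.
#' @return `write_spikes()` returns `path` invisibly; `read_spikes()` a
#'   tibble with attributes `n_neurons`, `duration_ms`.
#' @export
write_spikes <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_neurons: %d", result$n_neurons),
    sprintf("# duration_ms: %.17g", result$duration_ms),
    sprintf("# dt: %.17g", result$dt),
    sprintf("# seed: %d", result$seed),
    sprintf("# nu_ext: %.17g", result$drive$nu_ext),
    "neuron\ttime_ms"
  ), con)
  utils::write.table(result$spikes, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path, n = 12)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, ":"), hdr, fixed = TRUE)]
    as.numeric(sub(".*: *", "", ln))
  }
  sp <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  out <- tibble::tibble(neuron = as.integer(sp$neuron), time_ms = sp$time_ms)
  attr(out, "n_neurons") <- as.integer(val("n_neurons"))
  attr(out, "duration_ms") <- val("duration_ms")
  out
}
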