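#' Per-neuron firing rates and population moments
#'
#' Spike count divided by the interval length, per neuron, plus the
#' population mean, standard deviation and skewness (standardised third
#' central moment) of the rate distribution. Recurrent inhibition typically
#' produces positively skewed rate distributions: few fast neurons, many
#' slow ones.
#'
#' @param result A `sim_result` (or a spikes tibble with `neuron`,
#'   `time_ms`).
#' @param interval_ms Length-2 vector `(start, end)` in ms; defaults to the
#'   whole run.
#' @param n_neurons Number of neurons (taken from `result` if available).
#' @return A list of class `rate_statistics`: `rates` (tibble `neuron`,
#'   `rate`), `mean`, `sd`, `skewness` (`NA` when `sd` is 0).
#' @export
firing_rates <- function(result, interval_ms = NULL, n_neurons = NULL) {
  if (inherits(result, "sim_result")) {
    spikes <- result$spikes
    n_neurons <- n_neurons %||% result$n_neurons
    interval_ms <- interval_ms %||% c(0, result$duration_ms)
  } else {
    spikes <- result
    stopifnot(!is.null(n_neurons), !is.null(interval_ms))
  }
  len <- diff(interval_ms)
  if (len <= 0) stop("zero-length interval")
  sel <- spikes$time_ms > interval_ms[1] & spikes$time_ms <= interval_ms[2]
  counts <- tabulate(spikes$neuron[sel] + 1L, nbins = n_neurons)
  rates <- counts / (len / 1000)
  m <- mean(rates)
  s <- stats::sd(rates)
  skew <- if (is.na(s) || s == 0) NA_real_ else mean((rates - m)^3) / s^3
  structure(list(
    rates = tibble::tibble(neuron = 0:(n_neurons - 1L), rate = rates),
    mean = m, sd = s, skewness = skew,
    interval_ms = interval_ms
  ), class = "rate_statistics")
}

#' @export
print.rate_statistics <- function(x, ...) {
  cat(sprintf("<rate_statistics> mean %.3f spikes/s, sd %.3f, skewness %s (%d neurons)\n",
              x$mean, x$sd, format(x$skewness, digits = 3), nrow(x$rates)))
  invisible(x)
}

#' @method tidy rate_statistics
#' @export
tidy.rate_statistics <- function(x, ...) x$rates

#' @method glance rate_statistics
#' @export
glance.rate_statistics <- function(x, ...) {
  tibble::tibble(mean_rate = x$mean, sd_rate = x$sd, skewness = x$skewness)
}

#' Coefficient of variation of interspike intervals
#'
#' `sd(ISI) / mean(ISI)` for a single spike train: 0 for clock-like firing,
#' 1 for Poisson firing, above 1 for bursty trains. Undefined (returns `NA`)
#' for trains with fewer than 3 spikes.
#'
#' @param spike_times Numeric vector of spike times (any unit), sorted or
#'   not.
#' @return The CV of the ISIs, or `NA_real_` if fewer than 3 spikes.
#' @export
cv_isi <- function(spike_times) {
  if (length(spike_times) < 3) return(NA_real_)
  isi <- diff(sort(spike_times))
  stats::sd(isi) / mean(isi)
}

#' Per-neuron CV of interspike intervals
#'
#' @param result A `sim_result`.
#' @param min_spikes Neurons with fewer spikes get `NA` (excluded from
#'   population summaries; their number is reported in the
#'   `n_undefined` attribute).
#' @return A tibble `neuron`, `n_spikes`, `rate`, `cv_isi`.
#' @export
cv_isi_per_neuron <- function(result, min_spikes = 3) {
  stopifnot(inherits(result, "sim_result"))
  sp <- dplyr::arrange(result$spikes, .data$neuron, .data$time_ms)
  by_n <- dplyr::summarise(
    dplyr::group_by(sp, .data$neuron),
    n_spikes = dplyr::n(),
    cv_isi = cv_isi(.data$time_ms),
    .groups = "drop")
  all_n <- tibble::tibble(neuron = 0:(result$n_neurons - 1L))
  out <- dplyr::left_join(all_n, by_n, by = "neuron")
  out$n_spikes[is.na(out$n_spikes)] <- 0L
  out$cv_isi[out$n_spikes < min_spikes] <- NA_real_
  out$rate <- out$n_spikes / (result$duration_ms / 1000)
  attr(out, "n_undefined") <- sum(is.na(out$cv_isi))
  out[, c("neuron", "n_spikes", "rate", "cv_isi")]
}

#' Evoked-to-background response ratio
#'
#' `delta_response = evoked rate / background rate` for the stimulated
#' neurons, the evoked rate measured during the stimulus and the background
#' rate over the same neurons in pre-stimulus epochs. A zero background rate
#' makes the ratio undefined (`NA`, not infinity).
#'
#' @param evoked_rate,background_rate Rates in spikes/s (vectorised).
#' @return The ratio, `NA` where the background is 0.
#' @export
delta_response <- function(evoked_rate, background_rate) {
  stopifnot(all(evoked_rate >= 0, na.rm = TRUE))
  ifelse(background_rate > 0, evoked_rate / background_rate, NA_real_)
}

#' Fano factor time series across trials
#'
#' Variance-to-mean ratio of the stimulated-population spike count across
#' trials, per time window: a trial-to-trial reliability measure (1 for
#' Poisson counts, 0 for perfectly repeatable responses).
#'
#' @param counts A trials-by-windows matrix of spike counts (or a tibble
#'   `trial`, `window`, `count`).
#' @return A tibble `window`, `mean_count`, `var_count`, `fano` (`NA` with a
#'   flag column `zero_mean` where the mean count is 0).
#' @export
fano_factor <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::xtabs(count ~ trial + window, data = counts)
    counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                     dimnames = NULL)
  }
  if (nrow(counts) < 2) stop("Fano factor needs at least 2 trials")
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  tibble::tibble(
    window = seq_len(ncol(counts)) - 1L,
    mean_count = m, var_count = v,
    fano = ifelse(m > 0, v / m, NA_real_),
    zero_mean = m == 0
  )
}

#' Spectrum of pairwise spike-count correlations
#'
#' Pearson correlation coefficient for every neuron pair, computed on
#' trial-averaged spike counts in rectangular bins (default 100 ms). Neurons
#' with zero count variance are excluded (their number is reported).
#'
#' @param results A `sim_result`, or a list of them (trials; counts are
#'   averaged across trials before correlating).
#' @param neurons Zero-based indices of the neurons to correlate (default:
#'   all).
#' @param bin_ms Bin width, ms.
#' @param interval_ms Optional `(start, end)` restriction, ms.
#' @return A list of class `correlation_spectrum`: `pairs` (tibble
#'   `neuron_i`, `neuron_j`, `correlation`), `n_excluded` (zero-variance
#'   neurons), `quantiles` (5/25/50/75/95%).
#' @export
correlation_spectrum <- function(results, neurons = NULL, bin_ms = 100,
                                 interval_ms = NULL) {
  if (inherits(results, "sim_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  r1 <- results[[1]]
  interval_ms <- interval_ms %||% c(0, r1$duration_ms)
  neurons <- neurons %||% 0:(r1$n_neurons - 1L)
  stopifnot(length(neurons) >= 2)
  edges <- seq(interval_ms[1], interval_ms[2], by = bin_ms)
  if (length(edges) < 3) stop("need at least 2 bins")
  nb <- length(edges) - 1L
  acc <- matrix(0, nrow = nb, ncol = length(neurons))
  for (res in results) {
    sp <- res$spikes
    sel <- sp$neuron %in% neurons &
      sp$time_ms > interval_ms[1] & sp$time_ms <= interval_ms[2]
    sp <- sp[sel, ]
    bidx <- pmin(pmax(ceiling((sp$time_ms - interval_ms[1]) / bin_ms), 1L), nb)
    nidx <- match(sp$neuron, neurons)
    for (i in seq_along(bidx)) {
      acc[bidx[i], nidx[i]] <- acc[bidx[i], nidx[i]] + 1
    }
  }
  acc <- acc / length(results)
  vars <- apply(acc, 2, stats::var)
  keep <- which(vars > 0)
  n_excluded <- length(neurons) - length(keep)
  if (length(keep) < 2) {
    pairs <- tibble::tibble(neuron_i = integer(0), neuron_j = integer(0),
                            correlation = numeric(0))
  } else {
    cm <- stats::cor(acc[, keep, drop = FALSE])
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    pairs <- tibble::tibble(
      neuron_i = neurons[keep][ut[, 1]],
      neuron_j = neurons[keep][ut[, 2]],
      correlation = cm[ut]
    )
  }
  structure(list(
    pairs = pairs, n_excluded = n_excluded,
    quantiles = if (nrow(pairs) > 0)
      stats::quantile(pairs$correlation, c(0.05, 0.25, 0.5, 0.75, 0.95))
    else NULL
  ), class = "correlation_spectrum")
}

#' @export
print.correlation_spectrum <- function(x, ...) {
  cat(sprintf("<correlation_spectrum> %d pairs (%d zero-variance neurons excluded)\n",
              nrow(x$pairs), x$n_excluded))
  if (!is.null(x$quantiles)) print(round(x$quantiles, 4))
  invisible(x)
}

#' @method tidy correlation_spectrum
#' @export
tidy.correlation_spectrum <- function(x, ...) x$pairs

#' Classify the network state from bump statistics
#'
#' Three-way classification of the spatiotemporal regime:
#' * `"AI"` (asynchronous-irregular): mean per-frame bump count below
#'   `count_threshold` — no persistent spatial structure;
#' * `"WTA"` (winner-take-all): bumps present and the median normalised
#'   track lifespan above `lifespan_threshold` — stable periodic bumps;
#' * `"TA"` (transition activity): bumps present but short-lived.
#'
#' @param tracks A `bump_tracks` tibble from [track_bumps()].
#' @param bumpsets The corresponding list of `bump_set` tibbles.
#' @param count_threshold Mean bump count below which the state is AI.
#' @param lifespan_threshold Median normalised lifespan above which the
#'   state is WTA.
#' @param min_duration_ms Analyses shorter than this are refused (too little
#'   data to call a state).
#' @return A one-row tibble: `state` (factor AI/TA/WTA), `mean_count`,
#'   `median_lifespan_norm`.
#' @export
classify_state <- function(tracks, bumpsets, count_threshold = 1,
                           lifespan_threshold = 0.8,
                           min_duration_ms = 5000) {
  dur <- attr(tracks, "duration_ms") %||% (length(bumpsets) * 100)
  if (dur < min_duration_ms) {
    stop(sprintf("need at least %g ms of activity to classify a state (got %g ms)",
                 min_duration_ms, dur))
  }
  counts <- vapply(bumpsets, nrow, integer(1))
  mean_count <- mean(counts)
  med_life <- if (nrow(tracks) > 0) stats::median(tracks$lifespan_norm) else 0
  state <- if (mean_count < count_threshold) "AI"
  else if (med_life > lifespan_threshold) "WTA"
  else "TA"
  tibble::tibble(
    state = factor(state, levels = c("AI", "TA", "WTA")),
    mean_count = mean_count,
    median_lifespan_norm = med_life
  )
}
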