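#' Bin spikes into 2D activity frames
#'
#' Splits the run into disjoint windows (default 100 ms) and, for each,
#' arranges per-neuron spike counts on the `nrow x ncol` grid. The matrix is
#' indexed `[x + 1, y + 1]` for the neuron at grid position `(x, y)`
#' (`idx = x * ncol + y`). A binarised (any-spike indicator) variant is
#' available via `binary = TRUE`.
#'
#' @param result A `sim_result`, or a spikes tibble (`neuron`, `time_ms`).
#' @param geometry A [grid_geometry()]; defaults to the one stored in
#'   `result`.
#' @param window_ms Frame length, ms.
#' @param duration_ms Total duration (needed when passing a bare tibble).
#' @param binary If `TRUE`, clip counts at 1.
#' @return A list of class `activity_frames`: `frames` (list of matrices),
#'   `window_ms`, `duration_ms`, `geometry`.
#' @export
make_frames <- function(result, geometry = NULL, window_ms = 100,
                        duration_ms = NULL, binary = FALSE) {
  stopifnot(window_ms > 0)
  if (inherits(result, "sim_result")) {
    spikes <- result$spikes
    geometry <- geometry %||% result$geometry
    duration_ms <- duration_ms %||% result$duration_ms
  } else {
    spikes <- result
  }
  stopifnot(!is.null(geometry), !is.null(duration_ms))
  nframes <- floor(duration_ms / window_ms)
  nc <- geometry$ncol; nr <- geometry$nrow
  frames <- vector("list", nframes)
  fidx <- pmin(floor(spikes$time_ms / window_ms), nframes - 1)
  keep <- spikes$time_ms <= nframes * window_ms
  fidx <- fidx[keep]
  neuron <- spikes$neuron[keep]
  split_n <- split(neuron, factor(fidx, levels = 0:(nframes - 1)))
  for (f in seq_len(nframes)) {
    m <- matrix(0, nrow = nr, ncol = nc)
    nn <- split_n[[f]]
    if (length(nn) > 0) {
      counts <- tabulate(nn + 1L, nbins = geometry$n)
      # neuron idx = x*ncol + y -> matrix with x varying over rows
      m <- matrix(counts, nrow = nr, ncol = nc, byrow = TRUE)
    }
    if (binary) m <- (m > 0) * 1
    frames[[f]] <- m
  }
  structure(list(frames = frames, window_ms = window_ms,
                 duration_ms = duration_ms, geometry = geometry),
            class = "activity_frames")
}

#' @export
print.activity_frames <- function(x, ...) {
  cat(sprintf("<activity_frames> %d frames of %g ms, %d x %d grid\n",
              length(x$frames), x$window_ms, x$geometry$nrow, x$geometry$ncol))
  invisible(x)
}

#' Zero-integral 2D Mexican-hat (Ricker) kernel
#'
#' Discrete radially symmetric Ricker wavelet
#' `psi(r) = (1 - r^2 / (2 width^2)) * exp(-r^2 / (2 width^2))`
#' on a square support, rescaled so that the positive part sums to +1 and the
#' negative part to -1 (hence total integral 0): a spatially uniform frame
#' filters to exactly zero, so filtered activity is comparable across input
#' levels.
#'
#' @param width Width parameter in grid units (the positive lobe has radius
#'   `sqrt(2) * width`).
#' @param support Support radius in grid units (`>= 3 * width`); the kernel
#'   is a `(2 support + 1)` square array.
#' @return A matrix of class `ricker_kernel` with attribute `width`.
#' @export
build_ricker <- function(width, support = ceiling(4 * width)) {
  stopifnot(width > 0)
  if (support < 3 * width) stop("support must be at least 3 * width")
  s <- ceiling(support)
  ax <- -s:s
  r2 <- outer(ax^2, ax^2, `+`)
  psi <- (1 - r2 / (2 * width^2)) * exp(-r2 / (2 * width^2))
  pos <- sum(psi[psi > 0])
  neg <- -sum(psi[psi < 0])
  if (neg < 1e-12) stop("support too small: negative lobe not captured")
  psi[psi > 0] <- psi[psi > 0] / pos
  psi[psi < 0] <- psi[psi < 0] / neg
  structure(psi, class = c("ricker_kernel", "matrix", "array"), width = width)
}

# circular (torus) convolution of a frame with a centred kernel, via 2D FFT
torus_convolve <- function(frame, kernel) {
  nr <- nrow(frame); nc <- ncol(frame)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc) stop("kernel larger than the grid")
  big <- matrix(0, nr, nc)
  big[1:kr, 1:kc] <- kernel
  # centre the kernel at (1, 1) with wraparound
  sh <- (kr - 1) / 2
  big <- big[((0:(nr - 1) + sh) %% nr) + 1, ((0:(nc - 1) + sh) %% nc) + 1]
  Re(stats::fft(stats::fft(frame) * stats::fft(big), inverse = TRUE)) / (nr * nc)
}

# torus-aware circular mean of coordinates (0-based), optionally weighted
circular_mean_coord <- function(coord, len, w = NULL) {
  ang <- 2 * pi * coord / len
  if (is.null(w)) w <- rep(1, length(ang))
  m <- atan2(sum(w * sin(ang)), sum(w * cos(ang)))
  (m / (2 * pi) * len) %% len
}

# connected components on the torus (8-connectivity) over a logical matrix
torus_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- (p - 1L) %% nr
      c <- (p - 1L) %/% nr
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- (r + dr) %% nr
        cc <- (c + dc) %% nc
        q <- rr + cc * nr + 1L
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Detect activity bumps in one frame
#'
#' Convolves the frame with the Ricker kernel on the torus (circular
#' convolution), thresholds the filtered image, extracts torus-aware
#' connected components (8-connectivity) of at least `min_pixels` pixels and
#' returns one centroid per component, computed by circular averaging of
#' member-pixel coordinates weighted by the filtered activity.
#'
#' @param frame A count (or binary) matrix, as produced by [make_frames()].
#' @param kernel A [build_ricker()] kernel.
#' @param threshold_sd Detection threshold in robust noise units: pixels with
#'   filtered activity above `median + threshold_sd * 1.4826 * MAD` of the
#'   filtered image are bump candidates. The median/MAD noise floor is
#'   insensitive to the bumps themselves (which occupy a minority of pixels),
#'   so the same multiplier is comparable across input levels — a spatially
#'   featureless (asynchronous-irregular) frame yields no detections while
#'   bump peaks exceed the floor many times over. Classification is robust
#'   over `threshold_sd` in 4-6.
#' @param threshold Absolute threshold in filtered-activity units; overrides
#'   `threshold_sd` when given.
#' @param min_pixels Discard components smaller than this (suppresses
#'   single-pixel noise).
#' @return A tibble of class `bump_set` with one row per bump: `bump`, `cx`,
#'   `cy` (zero-based grid coordinates of the centroid), `n_pixels`,
#'   `peak_activity`; the member-pixel sets are kept in the
#'   `members` list-column (zero-based `(x, y)` matrices).
#' @export
detect_bumps <- function(frame, kernel, threshold_sd = 5, threshold = NULL,
                         min_pixels = 3) {
  filt <- torus_convolve(frame, kernel)
  # robust noise floor: MAD of the filtered image (insensitive to the bumps,
  # which occupy a minority of pixels) with a Poisson counting-noise lower
  # bound for sparse frames, where the median/MAD of a mostly-empty image
  # collapses to zero
  noise <- max(stats::mad(filt),
               sqrt(mean(frame) * sum(kernel^2)))
  # minimum-evidence floor: the peak must exceed anything two coincidently
  # active sites can produce (2.2 x the largest kernel weight), so isolated
  # spikes and chance pairs in near-empty frames never count as bumps
  thr <- threshold %||%
    (stats::median(filt) + max(threshold_sd * noise, 2.2 * max(kernel)))
  mask <- filt > thr
  lab <- torus_components(mask)
  nlab <- max(lab)
  rows <- list()
  if (nlab > 0) {
    for (b in seq_len(nlab)) {
      px <- which(lab == b, arr.ind = TRUE)
      if (nrow(px) < min_pixels) next
      # matrix rows index x (grid first coordinate), columns index y
      xs <- px[, 1] - 1L
      ys <- px[, 2] - 1L
      w <- filt[px] - thr
      rows[[length(rows) + 1]] <- tibble::tibble(
        cx = circular_mean_coord(xs, nrow(frame), w),
        cy = circular_mean_coord(ys, ncol(frame), w),
        n_pixels = nrow(px),
        peak_activity = max(filt[px]),
        members = list(cbind(x = xs, y = ys))
      )
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(cx = numeric(0), cy = numeric(0), n_pixels = integer(0),
                   peak_activity = numeric(0), members = list())
  }
  out <- tibble::add_column(out, bump = seq_len(nrow(out)), .before = 1)
  class(out) <- c("bump_set", class(out))
  out
}

#' Detect bumps in every frame
#'
#' @param frames An `activity_frames` object from [make_frames()].
#' @inheritParams detect_bumps
#' @return A list of `bump_set` tibbles, one per frame (in frame order).
#' @export
detect_bumps_frames <- function(frames, kernel, threshold_sd = 5,
                                threshold = NULL, min_pixels = 3) {
  stopifnot(inherits(frames, "activity_frames"))
  lapply(frames$frames, detect_bumps, kernel = kernel,
         threshold_sd = threshold_sd, threshold = threshold,
         min_pixels = min_pixels)
}

#' Track bumps across frames
#'
#' Greedy nearest-neighbour linking of bump centroids between consecutive
#' frames under the torus metric: the closest pair within `link_radius` is
#' linked first, then the next, and so on; unlinked centroids start new
#' tracks. Tracks tolerate no gap frames — a bump that vanishes and
#' reappears counts as a new bump.
#'
#' @param bumpsets A list of `bump_set` tibbles ordered by frame
#'   ([detect_bumps_frames()] output).
#' @param geometry A [grid_geometry()] matching the frames.
#' @param link_radius Maximum centroid displacement per frame, grid units.
#' @param window_ms Frame length (for normalised lifespans).
#' @param duration_ms Total analysed duration (defaults to
#'   `length(bumpsets) * window_ms`).
#' @return A tibble of class `bump_tracks`, one row per track: `track`,
#'   `first_frame` (zero-based), `lifespan` (frames), `lifespan_norm`
#'   (fraction of the run), and a `path` list-column of tibbles
#'   (`frame`, `cx`, `cy`).
#' @export
track_bumps <- function(bumpsets, geometry, link_radius = 3, window_ms = 100,
                        duration_ms = NULL) {
  duration_ms <- duration_ms %||% (length(bumpsets) * window_ms)
  open_tracks <- list()   # active: list(id, cx, cy)
  all_tracks <- list()    # id -> tibble(frame, cx, cy)
  next_id <- 1L
  for (f in seq_along(bumpsets)) {
    bs <- bumpsets[[f]]
    ncur <- nrow(bs)
    nopen <- length(open_tracks)
    assigned_cur <- rep(FALSE, ncur)
    assigned_open <- rep(FALSE, nopen)
    if (ncur > 0 && nopen > 0) {
      ocx <- vapply(open_tracks, `[[`, numeric(1), "cx")
      ocy <- vapply(open_tracks, `[[`, numeric(1), "cy")
      dm <- outer(seq_len(nopen), seq_len(ncur), function(i, j)
        torus_distance(ocx[i], ocy[i], bs$cx[j], bs$cy[j], geometry))
      repeat {
        m <- which.min(dm)
        if (length(m) == 0 || !is.finite(dm[m]) || dm[m] > link_radius) break
        i <- (m - 1) %% nopen + 1
        j <- (m - 1) %/% nopen + 1
        id <- open_tracks[[i]]$id
        all_tracks[[id]] <- dplyr::bind_rows(
          all_tracks[[id]],
          tibble::tibble(frame = f - 1L, cx = bs$cx[j], cy = bs$cy[j]))
        open_tracks[[i]] <- list(id = id, cx = bs$cx[j], cy = bs$cy[j])
        assigned_open[i] <- TRUE
        assigned_cur[j] <- TRUE
        dm[i, ] <- Inf
        dm[, j] <- Inf
      }
    }
    # unmatched current centroids start new tracks
    new_open <- list()
    for (j in which(!assigned_cur)) {
      id <- next_id
      next_id <- next_id + 1L
      all_tracks[[id]] <- tibble::tibble(frame = f - 1L, cx = bs$cx[j], cy = bs$cy[j])
      new_open[[length(new_open) + 1]] <- list(id = id, cx = bs$cx[j], cy = bs$cy[j])
    }
    # unmatched open tracks close (no gap tolerance)
    open_tracks <- c(open_tracks[assigned_open], new_open)
  }
  if (length(all_tracks) == 0) {
    out <- tibble::tibble(track = integer(0), first_frame = integer(0),
                          lifespan = integer(0), lifespan_norm = numeric(0),
                          path = list())
  } else {
    out <- tibble::tibble(
      track = seq_along(all_tracks),
      first_frame = vapply(all_tracks, function(p) p$frame[1], integer(1)),
      lifespan = vapply(all_tracks, nrow, integer(1)),
      lifespan_norm = vapply(all_tracks, nrow, integer(1)) * window_ms / duration_ms,
      path = all_tracks
    )
  }
  class(out) <- c("bump_tracks", class(out))
  attr(out, "n_frames") <- length(bumpsets)
  attr(out, "window_ms") <- window_ms
  attr(out, "duration_ms") <- duration_ms
  out
}

#' Summary statistics of detected bumps
#'
#' Per-frame bump-count statistics, the lifespan distribution split into
#' short / intermediate / long tertile bands, the median nearest-neighbour
#' centroid spacing (torus metric), and, when spikes are supplied, the mean
#' firing rate as a function of distance from the nearest bump centroid.
#'
#' @param tracks A `bump_tracks` tibble from [track_bumps()].
#' @param bumpsets The corresponding list of `bump_set` tibbles.
#' @param geometry A [grid_geometry()].
#' @param result Optional `sim_result` for the radial rate profile.
#' @return A list of class `bump_summary`: `count_mean`, `count_sd`,
#'   `counts` (per frame), `lifespan_bands` (tibble band/n/mean lifespan),
#'   `median_spacing` (grid units; `NA` with a `spacing_defined = FALSE`
#'   flag when no frame has two bumps), `radial_profile` (tibble or `NULL`).
#' @export
bump_summary <- function(tracks, bumpsets, geometry, result = NULL) {
  counts <- vapply(bumpsets, nrow, integer(1))
  nn <- unlist(lapply(bumpsets, function(bs) {
    if (nrow(bs) < 2) return(numeric(0))
    d <- outer(seq_len(nrow(bs)), seq_len(nrow(bs)), function(i, j)
      torus_distance(bs$cx[i], bs$cy[i], bs$cx[j], bs$cy[j], geometry))
    diag(d) <- Inf
    apply(d, 1, min)
  }))
  bands <- if (nrow(tracks) > 0) {
    q <- stats::quantile(tracks$lifespan_norm, c(1 / 3, 2 / 3), names = FALSE)
    brk <- unique(c(-Inf, q[1], q[2], Inf))
    band <- cut(tracks$lifespan_norm, brk,
                labels = c("short", "intermediate", "long")[seq_len(length(brk) - 1)])
    dplyr::summarise(dplyr::group_by(tibble::tibble(band = band,
                                                    lifespan_norm = tracks$lifespan_norm),
                                     band),
                     n = dplyr::n(),
                     mean_lifespan_norm = mean(lifespan_norm),
                     .groups = "drop")
  } else {
    tibble::tibble(band = character(0), n = integer(0),
                   mean_lifespan_norm = numeric(0))
  }
  radial <- NULL
  if (!is.null(result)) {
    radial <- radial_rate_profile(result, bumpsets, geometry)
  }
  structure(list(
    count_mean = mean(counts), count_sd = stats::sd(counts), counts = counts,
    lifespan_bands = bands,
    median_spacing = if (length(nn) > 0) stats::median(nn) else NA_real_,
    spacing_defined = length(nn) > 0,
    radial_profile = radial
  ), class = "bump_summary")
}

#' @export
print.bump_summary <- function(x, ...) {
  cat(sprintf("<bump_summary> %.2f +/- %.2f bumps per frame; median NN spacing %s grid units\n",
              x$count_mean, x$count_sd,
              if (x$spacing_defined) sprintf("%.2f", x$median_spacing) else "undefined (<2 bumps)"))
  print(x$lifespan_bands)
  invisible(x)
}

# mean firing rate vs torus distance from the nearest bump centroid
radial_rate_profile <- function(result, bumpsets, geometry, breaks = NULL) {
  breaks <- breaks %||% seq(0, floor(min(geometry$ncol, geometry$nrow) / 2), by = 1)
  rates <- neuron_rates_vector(result)
  xy <- xy_from_idx(0:(geometry$n - 1), geometry)
  cents <- dplyr::bind_rows(lapply(bumpsets, function(b) b[, c("cx", "cy")]))
  cents <- unique(cents)
  if (nrow(cents) == 0) return(NULL)
  dmin <- rep(Inf, geometry$n)
  for (i in seq_len(nrow(cents))) {
    dmin <- pmin(dmin, torus_distance(xy$x, xy$y, cents$cx[i], cents$cy[i], geometry))
  }
  bin <- cut(dmin, breaks, include.lowest = TRUE)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, rate = rates), bin),
    mean_rate = mean(rate), n_neurons = dplyr::n(), .groups = "drop")
}

# per-neuron firing rate vector in spikes/s, over the whole run
neuron_rates_vector <- function(result) {
  counts <- tabulate(result$spikes$neuron + 1L, nbins = result$n_neurons)
  counts / (result$duration_ms / 1000)
}
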