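#' @importFrom dplyr %>%
#' @importFrom rlang .data
NULL

# Draw (dx, dy) integer grid offsets by polar sampling: an angle phi uniform
# on (-pi, pi] and a radius r from the kernel's radial law, rounded to the
# nearest grid offset. Offsets equal to (0, 0) would be self-connections and
# are redrawn by the callers.
polar_offsets <- function(m, kernel) {
  phi <- stats::runif(m, -pi, pi)
  r <- kernel_sample_radius(m, kernel)
  list(dx = as.integer(round(r * sin(phi))),
       dy = as.integer(round(r * cos(phi))))
}

#' Sample synaptic targets for one source neuron
#'
#' Draws `k` targets for a neuron by polar sampling: angle `phi ~ U(-pi, pi)`,
#' radius from the kernel's radial distribution, continuous offsets rounded to
#' the nearest integer grid offset and wrapped on the torus. Draws landing on
#' the source itself are rejected and redrawn (no autapses); repeated targets
#' (multapses) are permitted.
#'
#' Uses the current R RNG stream; call `set.seed()` (or use [build_network()])
#' for reproducibility.
#'
#' @param source Zero-based source neuron index.
#' @param k Number of targets (out-degree).
#' @param kernel A [kernel_spec()].
#' @param geometry A [grid_geometry()].
#' @param max_redraws Abort after this many rejection rounds (guards against
#'   kernels that concentrate nearly all mass on the source site).
#' @return Integer vector of `k` zero-based target indices.
#' @export
sample_targets <- function(source, k, kernel, geometry = grid_geometry(),
                           max_redraws = 1000L) {
  stopifnot(k >= 0, source >= 0, source < geometry$n)
  if (k == 0) return(integer(0))
  off <- polar_offsets(k, kernel)
  dx <- off$dx; dy <- off$dy
  tries <- 0L
  repeat {
    bad <- which(dx == 0L & dy == 0L)
    if (length(bad) == 0) break
    tries <- tries + 1L
    if (tries > max_redraws) {
      stop(sprintf("target sampling for source %d did not converge after %d redraw rounds: kernel places almost all mass on the source site",
                   source, max_redraws))
    }
    re <- polar_offsets(length(bad), kernel)
    dx[bad] <- re$dx; dy[bad] <- re$dy
  }
  sx <- source %/% geometry$ncol
  sy <- source %% geometry$ncol
  idx_from_xy(sx + dx, sy + dy, geometry)
}

#' Build the full distance-dependent network
#'
#' Wires every neuron on the torus grid to exactly `k` targets using the
#' polar-sampling rule of [sample_targets()], under a single seeded RNG
#' stream. With the defaults (100 x 100 grid, `k = 1000`) this reproduces the
#' reference architecture: 10^7 inhibitory edges, an overall connection
#' probability of `k / N = 10%`, no self-connections, multapses allowed.
#'
#' @param geometry A [grid_geometry()].
#' @param kernel A [kernel_spec()].
#' @param k Out-degree of every neuron (default 1000).
#' @param seed Integer seed for the wiring RNG stream.
#' @param max_redraws Per-round cap on self-connection redraws.
#' @return An object of class `connectivity_table`: list with `targets`
#'   (integer matrix, `k` rows by `N` columns, zero-based target indices;
#'   column `j` holds the targets of source `j - 1`), `k`, `seed`, `geometry`,
#'   `kernel`.
#' @examples
#' net <- build_network(grid_geometry(20, 20), kernel_spec("gamma", 3, 1.5),
#'                      k = 40, seed = 1)
#' @export
build_network <- function(geometry = grid_geometry(),
                          kernel = kernel_spec("gamma"),
                          k = 1000L, seed = 1L, max_redraws = 1000L) {
  stopifnot(k >= 0, k == round(k))
  k <- as.integer(k)
  n <- geometry$n
  old_seed_exists <- exists(".Random.seed", envir = globalenv())
  if (old_seed_exists) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (old_seed_exists) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  m <- n * k
  off <- polar_offsets(m, kernel)
  dx <- off$dx; dy <- off$dy
  tries <- 0L
  repeat {
    bad <- which(dx == 0L & dy == 0L)
    if (length(bad) == 0) break
    tries <- tries + 1L
    if (tries > max_redraws) {
      src_bad <- unique((bad - 1L) %/% k)
      stop(sprintf("wiring did not converge after %d redraw rounds (first offending source: %d)",
                   max_redraws, src_bad[1]))
    }
    re <- polar_offsets(length(bad), kernel)
    dx[bad] <- re$dx; dy[bad] <- re$dy
  }
  source <- rep.int(0:(n - 1L), rep.int(k, n))
  sx <- source %/% geometry$ncol
  sy <- source %% geometry$ncol
  tgt <- idx_from_xy(sx + dx, sy + dy, geometry)
  structure(
    list(targets = matrix(as.integer(tgt), nrow = k, ncol = n),
         k = k, seed = as.integer(seed), geometry = geometry, kernel = kernel),
    class = "connectivity_table"
  )
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat(sprintf("<connectivity_table> %d neurons, out-degree %d (%d edges), seed %d\n",
              x$geometry$n, x$k, x$geometry$n * x$k, x$seed))
  print(x$kernel)
  invisible(x)
}

#' Connectivity table as a tidy edge list
#'
#' @param x A `connectivity_table`.
#' @param ... Unused.
#' @return A tibble with zero-based columns `source_idx`, `target_idx`
#'   (one row per edge, multapses repeated).
#' @method tidy connectivity_table
#' @export
tidy.connectivity_table <- function(x, ...) {
  n <- x$geometry$n
  tibble::tibble(
    source_idx = rep.int(0:(n - 1L), rep.int(x$k, n)),
    target_idx = as.integer(x$targets)
  )
}

#' Connection probability as a function of torus distance
#'
#' Bins all realized edges by the torus distance between source and target
#' and divides, per bin, by the number of *possible* ordered pairs at that
#' distance (`N` times the number of grid offsets falling in the bin). For a
#' Gaussian kernel the profile decays monotonically from zero distance; for a
#' gamma kernel with `n > 1` it peaks at a nonzero distance (off-centre
#' inhibition).
#'
#' @param table A `connectivity_table` from [build_network()].
#' @param breaks Distance bin edges in grid units (default unit bins up to
#'   half the grid extent).
#' @return A tibble with one row per bin: `distance` (bin midpoint),
#'   `realized` (edge count), `possible` (ordered site pairs), `probability`,
#'   and `empty` (flag: no possible pairs in the bin).
#' @export
empirical_distance_profile <- function(table, breaks = NULL) {
  stopifnot(inherits(table, "connectivity_table"))
  geom <- table$geometry
  if (is.null(breaks)) breaks <- seq(0, floor(min(geom$ncol, geom$nrow) / 2), by = 1)

  edges <- tidy.connectivity_table(table)
  sx <- edges$source_idx %/% geom$ncol; sy <- edges$source_idx %% geom$ncol
  tx <- edges$target_idx %/% geom$ncol; ty <- edges$target_idx %% geom$ncol
  d <- torus_distance(sx, sy, tx, ty, geom)

  # every offset (dx, dy) is realizable from each of the N sources
  alldx <- torus_offset(0:(geom$nrow - 1L), geom$nrow)
  alldy <- torus_offset(0:(geom$ncol - 1L), geom$ncol)
  offd <- as.vector(sqrt(outer(alldx^2, alldy^2, `+`)))
  offd <- offd[offd > 0] # the zero offset (self) is not a possible pair

  cut_r <- cut(d, breaks, include.lowest = FALSE, right = TRUE)
  cut_p <- cut(offd, breaks, include.lowest = FALSE, right = TRUE)
  realized <- as.vector(table(cut_r))
  possible <- as.vector(table(cut_p)) * geom$n
  mid <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  tibble::tibble(
    distance = mid,
    realized = realized,
    possible = possible,
    probability = ifelse(possible > 0, realized / possible, 0),
    empty = possible == 0
  )
}

#' Write / read an edge list as plain text
#'
#' Tab-separated table with columns `source_idx`, `target_idx` (zero-based)
#' and `#`-prefixed header lines carrying the geometry, kernel, out-degree
#' and seed, so a table can be rebuilt losslessly.
#'
#' @param table A `connectivity_table`.
#' @param path Output file path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a `connectivity_table`.
#' @export
write_edge_list <- function(table, path) {
  stopifnot(inherits(table, "connectivity_table"))
  geom <- table$geometry
  ker <- table$kernel
  kerline <- if (ker$kind == "gamma") {
    sprintf("# kernel: gamma n=%.17g theta=%.17g", ker$n, ker$theta)
  } else {
    sprintf("# kernel: gaussian sigma=%.17g", ker$sigma)
  }
  header <- c(
    sprintf("# geometry: ncol=%d nrow=%d spacing_um=%.17g", geom$ncol, geom$nrow, geom$spacing_um),
    kerline,
    sprintf("# out_degree: %d", table$k),
    sprintf("# seed: %d", table$seed),
    "source_idx\ttarget_idx"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  edges <- tidy.connectivity_table(table)
  utils::write.table(edges, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param path Input file path.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  grab <- function(pat) {
    ln <- hdr[grepl(pat, hdr)]
    stopifnot(length(ln) == 1)
    ln
  }
  gl <- grab("geometry:")
  num <- function(line, key) as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", line))
  geom <- grid_geometry(num(gl, "ncol"), num(gl, "nrow"), num(gl, "spacing_um"))
  kl <- grab("kernel:")
  kernel <- if (grepl("gamma", kl)) {
    kernel_spec("gamma", n = num(kl, "n"), theta = num(kl, "theta"))
  } else {
    kernel_spec("gaussian", sigma = num(kl, "sigma"))
  }
  k <- as.integer(sub(".*out_degree: *([0-9]+).*", "\\1", grab("out_degree:")))
  seed <- as.integer(sub(".*seed: *(-?[0-9]+).*", "\\1", grab("seed:")))
  edges <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  stopifnot(nrow(edges) == geom$n * k)
  ord <- order(edges$source_idx)
  structure(
    list(targets = matrix(as.integer(edges$target_idx[ord]), nrow = k, ncol = geom$n),
         k = k, seed = seed, geometry = geom, kernel = kernel),
    class = "connectivity_table"
  )
}

#' Read a network configuration block from YAML
#'
#' Expects keys `geometry` (`ncol`, `nrow`, `spacing_um`), `kernel` (`kind`
#' plus `n`/`theta` or `sigma`), `out_degree`, `seed`; any field may be
#' omitted and falls back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `geometry`, `kernel`, `out_degree`, `seed`.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry %||% list()
  geometry <- grid_geometry(g$ncol %||% 100L, g$nrow %||% 100L, g$spacing_um %||% 10)
  kc <- cfg$kernel %||% list()
  kind <- kc$kind %||% "gamma"
  kernel <- if (kind == "gamma") {
    kernel_spec("gamma", n = kc$n %||% 3, theta = kc$theta %||% 3)
  } else {
    kernel_spec("gaussian", sigma = kc$sigma %||% 8)
  }
  list(geometry = geometry, kernel = kernel,
       out_degree = as.integer(cfg$out_degree %||% 1000L),
       seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
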