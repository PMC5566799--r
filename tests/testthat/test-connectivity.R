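test_that("sample_targets returns exactly k targets, never the source, for both kernels", {
  geom <- grid_geometry(50, 50)
  for (ker in list(kernel_spec("gamma", 8, 0.5), kernel_spec("gaussian", sigma = 4))) {
    set.seed(3)
    expect_identical(sample_targets(17, 0, ker, geom), integer(0))
    tg <- sample_targets(17, 1000, ker, geom)
    expect_length(tg, 1000)
    expect_false(any(tg == 17))
    expect_true(all(tg >= 0 & tg < geom$n))
  }
})

test_that("a kernel concentrating all mass on the source aborts with a diagnostic", {
  geom <- grid_geometry(50, 50)
  degenerate <- kernel_spec("gaussian", sigma = 1e-9)
  set.seed(1)
  expect_error(sample_targets(5, 10, degenerate, geom, max_redraws = 50),
               "did not converge")
  expect_error(build_network(grid_geometry(5, 5), degenerate, k = 2, seed = 1,
                             max_redraws = 20),
               "did not converge")
})

test_that("radial draws follow the kernel's density: off-centre mode for gamma n > 1", {
  ker <- kernel_spec("gamma", 8, 0.5)
  set.seed(11)
  r <- kernel_sample_radius(1e5, ker)
  h <- hist(r, breaks = seq(0, ceiling(max(r)), by = 0.5), plot = FALSE)
  mode_bin <- h$mids[which.max(h$counts)]
  expect_lt(abs(mode_bin - kernel_radial_mode(ker)), 0.5 + 1e-9)
  # mass near zero far below the mode bin
  expect_lt(h$counts[1], 0.2 * max(h$counts))
  # histogram matches the analytic density (chi-square on pooled bins)
  p_bins <- diff(stats::pgamma(h$breaks, shape = 8, scale = 0.5))
  keep <- p_bins * 1e5 >= 5
  chi <- suppressWarnings(stats::chisq.test(h$counts[keep],
                                            p = p_bins[keep] / sum(p_bins[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("build_network has exact out-degree, no autapses, and is seed-reproducible", {
  geom <- grid_geometry(20, 20)
  ker <- kernel_spec("gamma", 8, 0.5)
  net <- build_network(geom, ker, k = 50, seed = 9)
  expect_identical(dim(net$targets), c(50L, 400L))
  self <- matrix(0:(geom$n - 1), nrow = 50, ncol = geom$n, byrow = TRUE)
  expect_false(any(net$targets == self))

  net2 <- build_network(geom, ker, k = 50, seed = 9)
  expect_identical(net$targets, net2$targets)
  net3 <- build_network(geom, ker, k = 50, seed = 10)
  expect_false(identical(net$targets, net3$targets))

  tiny <- build_network(grid_geometry(3, 3), kernel_spec("gaussian", sigma = 1),
                        k = 1, seed = 2)
  expect_identical(dim(tiny$targets), c(1L, 9L))
  expect_false(any(tiny$targets == matrix(0:8, nrow = 1)))
})

test_that("distance profiles have the expected on-/off-centre shapes and are isotropic", {
  geom <- grid_geometry(50, 50)
  gnet <- build_network(geom, kernel_spec("gaussian", sigma = 4), k = 250, seed = 5)
  prof_g <- empirical_distance_profile(gnet)
  pg <- prof_g$probability[!prof_g$empty & prof_g$distance < 12]
  # monotone nonincreasing within sampling error: allow tiny upticks
  expect_true(all(diff(pg) < 0.05 * max(pg)),
              label = "gaussian profile nonincreasing with distance")
  expect_gt(pg[1], utils::tail(pg, 1))

  ker <- kernel_spec("gamma", 8, 0.75)
  anet <- build_network(geom, ker, k = 250, seed = 5)
  prof_a <- empirical_distance_profile(anet)
  pa <- prof_a$probability[!prof_a$empty]
  expect_gt(which.max(pa), 2) # per-pair probability peaks off centre

  # edge-distance histogram mode matches the radial gamma mode (n-1)*theta
  edges <- tidy(anet)
  sx <- edges$source_idx %/% 50; sy <- edges$source_idx %% 50
  tx <- edges$target_idx %/% 50; ty <- edges$target_idx %% 50
  d <- torus_distance(sx, sy, tx, ty, geom)
  h <- hist(d, breaks = seq(0, 40, 1), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - kernel_radial_mode(ker)), 1.01)

  # isotropy: pure x-axis and y-axis offsets are equally likely
  dx <- abs((tx - sx + 25) %% 50 - 25)
  dy <- abs((ty - sy + 25) %% 50 - 25)
  on_x <- sum(dy == 0 & dx > 0)
  on_y <- sum(dx == 0 & dy > 0)
  expect_lt(abs(on_x - on_y) / sqrt(on_x + on_y), 4) # ~4 sigma binomial
})

test_that("wiring is translation invariant: pooled offsets match a single-source law", {
  geom <- grid_geometry(50, 50)
  ker <- kernel_spec("gamma", 8, 0.75)
  net <- build_network(geom, ker, k = 40, seed = 13)
  edges <- tidy(net)
  sx <- edges$source_idx %/% 50; sy <- edges$source_idx %% 50
  tx <- edges$target_idx %/% 50; ty <- edges$target_idx %% 50
  dx <- (tx - sx) %% 50; dy <- (ty - sy) %% 50
  pooled <- table(factor(dx * 50 + dy, levels = 0:2499))

  set.seed(99)
  single <- sample_targets(0, 1e5, ker, geom)
  ref <- table(factor(single, levels = 0:2499))
  keep <- ref >= 25 & pooled >= 25
  # two-sample homogeneity test: both are random draws from the offset law
  chi <- suppressWarnings(
    stats::chisq.test(rbind(as.vector(pooled[keep]), as.vector(ref[keep]))))
  expect_gt(chi$p.value, 0.01)
})

test_that("edge lists and YAML configs survive a write/read round trip", {
  net <- tiny_net()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_identical(back$targets, net$targets)
  expect_identical(back$k, net$k)
  expect_identical(back$seed, net$seed)
  expect_equal(back$geometry$ncol, net$geometry$ncol)
  expect_equal(back$kernel$n, net$kernel$n)

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry:", "  ncol: 40", "  nrow: 40", "  spacing_um: 10",
    "kernel:", "  kind: gamma", "  n: 8", "  theta: 0.5",
    "out_degree: 100", "seed: 4"), cfg)
  conf <- read_network_config(cfg)
  expect_equal(conf$geometry$n, 1600L)
  expect_equal(conf$kernel$theta, 0.5)
  expect_identical(conf$out_degree, 100L)
})
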