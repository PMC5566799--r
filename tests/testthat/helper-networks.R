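# Shared, lazily built simulation fixtures. Building networks and running the
# reduced-preset simulations dominates suite run time, so anything used by
# more than one test lives here and is computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_once <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

reduced_gamma_net <- function() {
  fixture_once("reduced_gamma_net", function() {
    p <- reduced_preset("gamma")
    build_network(p$geometry, p$kernel, p$k, seed = 42)
  })
}

reduced_gaussian_net <- function() {
  fixture_once("reduced_gaussian_net", function() {
    p <- reduced_preset("gaussian")
    build_network(p$geometry, p$kernel, p$k, seed = 42)
  })
}

# 10 s winner-take-all run on the reduced gamma preset (WTA drive point)
wta_sim <- function() {
  fixture_once("wta_sim", function() {
    drive <- reduced_preset("gamma")$drive_grid[3]
    simulate_network(reduced_gamma_net(), drive = drive,
                     duration_ms = 10000, seed = 7)
  })
}

# 5 s runs at the AI and TA drive points of the reduced gamma preset
ai_sim <- function() {
  fixture_once("ai_sim", function() {
    simulate_network(reduced_gamma_net(),
                     drive = reduced_preset("gamma")$drive_grid[1],
                     duration_ms = 5000, seed = 7)
  })
}

ta_sim <- function() {
  fixture_once("ta_sim", function() {
    simulate_network(reduced_gamma_net(),
                     drive = reduced_preset("gamma")$drive_grid[2],
                     duration_ms = 5000, seed = 7)
  })
}

gaussian_sim <- function(nu) {
  fixture_once(paste0("gaussian_sim_", nu), function() {
    simulate_network(reduced_gaussian_net(), drive = nu,
                     duration_ms = 5000, seed = 7)
  })
}

# small 10x10 network for fast mechanical tests
tiny_net <- function() {
  fixture_once("tiny_net", function() {
    build_network(grid_geometry(10, 10), kernel_spec("gamma", 8, 0.5),
                  k = 20, seed = 1)
  })
}
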