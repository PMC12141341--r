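test_that("cyclic topology wires each neuron to the preceding fan_in neurons", {
  pre <- build_cyclic_network(5, 3)
  expect_identical(pre$d, c("a", "b", "c"))
  expect_identical(pre$a, c("c", "d", "e"))  # wrap-around
  expect_identical(pre$b, c("a", "d", "e"))
  expect_error(build_cyclic_network(5, 5), class = "invalid_topology")
  expect_error(build_cyclic_network(5, 0), class = "invalid_topology")
})

test_that("hue maps to LGN nodes as a one-of-three code", {
  expect_identical(hue_to_lgn("green"), c(1L, 2L))
  expect_identical(hue_to_lgn("red"), 2L)    # node driving neuron b
  expect_identical(hue_to_lgn("blue"), 1L)   # node driving neuron a
  expect_identical(hue_to_lgn("none"), integer(0))
  expect_error(hue_to_lgn("ultraviolet"), class = "invalid_stimulus")
})

test_that("LGN spike trains are pure functions of (seed, node) with the nominal rate", {
  p <- lgn_params(100, 2)
  expect_identical(generate_lgn_spike_train(p, 1, 42, 100, 0), numeric(0))
  t1 <- generate_lgn_spike_train(p, 2, 42, 100, 300)
  t2 <- generate_lgn_spike_train(p, 2, 42, 100, 300)
  expect_identical(t1, t2)
  # distinct nodes and seeds give distinct streams
  expect_false(identical(t1, generate_lgn_spike_train(p, 1, 42, 100, 300)))
  # refractory dead time is respected
  expect_gte(min(diff(t1)), p$refractory)
  # mean count over many seeds matches rate * duration (30 +- 1)
  counts <- vapply(1:1000, function(s) {
    length(generate_lgn_spike_train(p, 1, s, 0, 300))
  }, numeric(1))
  expect_gt(mean(counts), 29)
  expect_lt(mean(counts), 31)
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_lgn_spike_train(lgn_params(), 1, 5, 0, 100))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("hue computation: green ignites all neurons, red and blue only the direct target", {
  cfg <- ref_config()
  g <- run_simulation(cfg, hue_stimulus("green"), 500, seed = 1)
  expect_identical(n_firing_neurons(g), 5L)
  r <- run_simulation(cfg, hue_stimulus("red"), 500, seed = 1)
  expect_identical(n_firing_neurons(r), 1L)
  expect_gt(length(r$spikes$b), 0)
  b <- run_simulation(cfg, hue_stimulus("blue"), 500, seed = 1)
  expect_identical(n_firing_neurons(b), 1L)
  expect_gt(length(b$spikes$a), 0)
  n <- run_simulation(cfg, hue_stimulus("none", 100, 0), 500, seed = 1)
  expect_identical(n_firing_neurons(n), 0L)
  expect_lt(max(abs(n$V + 70)), 1)
})

test_that("runs are bitwise deterministic given identical inputs", {
  cfg <- ref_config()
  a <- run_simulation(cfg, hue_stimulus("green", 50, 200), 300, seed = 5)
  b <- run_simulation(cfg, hue_stimulus("green", 50, 200), 300, seed = 5)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$config_digest, b$config_digest)
})

test_that("open-loop runs carry a zero clamp-current trace", {
  res <- run_simulation(ref_config(), hue_stimulus("red", 50, 200), 300, seed = 2)
  expect_true(all(res$I_vc == 0))
})

test_that("network activity ceases soon after stimulus offset (depression guard)", {
  cfg <- ref_config()
  for (s in 1:3) {
    res <- run_simulation(cfg, hue_stimulus("green", 100, 300), 700, seed = s)
    expect_lt(max(unlist(res$spikes)), 400 + 200)
  }
})

test_that("detect_spikes counts upward crossings once per event", {
  expect_identical(detect_spikes(rep(-70, 1000)), numeric(0))
  # single spike-like waveform
  t <- seq(0, 20, by = 0.025)
  wave <- -70 + 110 * exp(-((t - 10) / 0.5)^2)
  expect_length(detect_spikes(wave, 0, 0.025), 1)
  # double crossing 1 ms apart collapses to one event under the 2 ms rule
  tr <- rep(-70, 400)
  tr[100:110] <- 10
  tr[140:150] <- 10
  expect_length(detect_spikes(tr, 0, 0.025, min_separation = 2), 1)
  expect_length(detect_spikes(tr, 0, 0.025, min_separation = 0.5), 2)
})

test_that("offline spike detection reproduces the simulator's online detection", {
  res <- run_simulation(ref_config(), hue_stimulus("green", 50, 200), 300, seed = 9)
  for (nm in colnames(res$V)) {
    expect_equal(detect_spikes(res$V[, nm], 0, res$dt), res$spikes[[nm]])
  }
})

test_that("invalid network configurations are rejected", {
  expect_error(network_config(lgn_targets = c(1L, 1L)),
               class = "invalid_topology")
  expect_error(network_config(lgn_targets = c(1L, 9L)),
               class = "invalid_topology")
  expect_error(run_simulation(ref_config(), hue_stimulus("green", 100, 300),
                              duration = 200),
               class = "invalid_stimulus")
})
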