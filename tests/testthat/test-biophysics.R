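test_that("rest is a fixed point of the neuron dynamics", {
  np <- neuron_params()
  tr <- simulate_neuron(np, rep(0, 20000))  # 500 ms
  expect_lt(max(abs(tr$V - np$leak_reversal)), 0.01)
  expect_length(tr$spikes, 0)
})

test_that("a sustained 300 pA step evokes spikes, and spike counts agree with a 10x finer integration", {
  np <- neuron_params()
  coarse <- simulate_neuron(np, rep(300, 20000), dt = 0.025)
  fine <- simulate_neuron(np, rep(300, 200000), dt = 0.0025)
  expect_gte(length(coarse$spikes), 1)
  expect_gt(max(coarse$V), 0)
  expect_identical(length(coarse$spikes), length(fine$spikes))
})

test_that("spike counts match the 10x finer reference on random input traces", {
  np <- neuron_params()
  set.seed(42)
  for (r in 1:10) {
    seg <- rep(runif(50, 0, 400), each = 400)  # 10 ms segments, 500 ms total
    coarse <- simulate_neuron(np, seg, dt = 0.025)
    fine <- simulate_neuron(np, rep(seg, each = 10), dt = 0.0025)
    expect_identical(length(coarse$spikes), length(fine$spikes))
  }
})

test_that("gate variables stay in [0, 1] under randomized current drive", {
  np <- neuron_params()
  set.seed(7)
  for (r in 1:3) {
    seg <- rep(runif(1000, -200, 600), each = 400)  # 10 s of 10 ms segments
    tr <- simulate_neuron(np, seg)
    for (g in c("m", "h", "n")) {
      expect_gte(min(tr[[g]]), 0)
      expect_lte(max(tr[[g]]), 1)
    }
  }
})

test_that("step_neuron rejects non-finite state with an informative signal", {
  np <- neuron_params()
  st <- neuron_state(params = np)
  st[["V"]] <- NaN
  expect_error(step_neuron(st, np, 0, 0.025), class = "integration_failure")
  expect_error(step_neuron(st, np, 0, 0.025), "V")
})

test_that("input resistance measures 50 MOhm and scales with the leak", {
  expect_equal(measure_input_resistance(neuron_params(), -20), 50,
               tolerance = 0.05)
  expect_equal(
    measure_input_resistance(neuron_params(leak_conductance = 40), -20), 25,
    tolerance = 0.05)
})

test_that("input resistance is insensitive to the integration step", {
  np <- neuron_params()
  r1 <- measure_input_resistance(np, dt = 0.025)
  r2 <- measure_input_resistance(np, dt = 0.0025)
  expect_lt(abs(r1 - r2) / r1, 0.01)
})

test_that("invalid probes are rejected", {
  np <- neuron_params()
  expect_error(measure_input_resistance(np, 0), class = "invalid_probe")
  expect_error(measure_input_resistance(np, 20), class = "invalid_probe")
  expect_error(measure_input_resistance(np, -200), class = "invalid_probe")
})

test_that("depression follows the multiplicative event rule exactly", {
  sp <- synapse_params(depressing = TRUE)
  st <- synapse_state()
  st1 <- synapse_event(st, sp)
  expect_identical(st1$strength, 0.5)
  st2 <- synapse_event(st1, sp)
  expect_identical(st2$strength, 0.25)
  # k rapid events give factor^k with no drift
  stk <- synapse_state()
  for (k in 1:8) stk <- synapse_event(stk, sp)
  expect_identical(stk$strength, 0.5^8)
})

test_that("non-depressing synapses keep full strength across events", {
  sp <- synapse_params(depressing = FALSE)
  st <- synapse_event(synapse_state(), sp)
  expect_identical(st$strength, 1)
})

test_that("strength recovers exponentially toward 1", {
  sp <- synapse_params()
  st <- synapse_state(strength = 0.5)
  # closed form after one recovery_tau: 1 - 0.5/e
  st1 <- synapse_step(st, sp, 1000)
  expect_equal(st1$strength, 1 - 0.5 * exp(-1), tolerance = 1e-12)
  # long limit
  st2 <- synapse_step(st, sp, 1e6)
  expect_equal(st2$strength, 1, tolerance = 1e-9)
})

test_that("the conductance transient peaks at rise_time with the nominal amplitude and decays with decay_tau", {
  sp <- synapse_params()
  tr <- synapse_transient(sp, duration = 80)
  peak_idx <- which.max(tr$g)
  expect_equal(tr$time[peak_idx], 2, tolerance = 0.1)
  expect_equal(tr$g[peak_idx], 5, tolerance = 0.02)
  tail <- tr[tr$time >= tr$time[peak_idx] + 5, ]
  fit <- lm(log(g) ~ time, data = tail)
  expect_equal(-1 / coef(fit)[["time"]], 10, tolerance = 0.02)
})

test_that("synaptic current follows g * (E - V)", {
  sp <- synapse_params()
  st <- synapse_event(synapse_state(), sp)
  # at reversal no current flows
  expect_identical(synaptic_current(st, sp, sp$reversal), 0)
  # zero conductance state
  expect_identical(synaptic_current(synapse_state(), sp, -70), 0)
  # 5 nS at -70 mV against a 0 mV reversal
  st5 <- synapse_state(rise_component = 0, decay_component = 5)
  expect_equal(synaptic_current(st5, sp, -70), 350)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(capacitance = -1), class = "invalid_params")
  expect_error(synapse_params(rise_time = 12, decay_tau = 10),
               class = "invalid_params")
  expect_error(synapse_params(depression_factor = 0),
               class = "invalid_params")
  expect_error(synapse_state(strength = 1.5), class = "invalid_state")
  # calibrated leak matches the 50 MOhm input-resistance target within 5%
  np <- neuron_params()
  expect_equal(1000 / np$leak_conductance, 50, tolerance = 0.05)
})
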