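test_that("a recording stores the open-loop voltages bit for bit", {
  cfg <- ref_config()
  rec <- green_recording()
  res <- run_simulation(cfg, hue_stimulus("green"), 500, seed = 11)
  expect_identical(rec$V, res$V)
  expect_identical(rec$spikes, res$spikes)
  rec2 <- record_reference_run(cfg, hue_stimulus("green"), 500, seed = 11)
  expect_identical(rec$V, rec2$V)
})

test_that("the clamp current follows Ohm's law in the commanded direction", {
  expect_identical(feedback_clamp_current(-55, -55, 0.1), 0)
  expect_equal(feedback_clamp_current(-54, -55, 0.1), 10000)
  expect_equal(feedback_clamp_current(-56, -55, 0.1), -10000)
  expect_error(feedback_clamp_current(0, 0, 0), class = "invalid_params")
})

test_that("a clamped neuron snaps to a step command within a few clamp time constants", {
  cfg <- ref_config()
  # synthetic command: rest, then a 10 mV step at 10 ms
  n_steps <- round(100 / cfg$dt)
  cmd <- matrix(-70, n_steps + 1, cfg$n_cortical)
  step_at <- round(10 / cfg$dt)
  cmd[(step_at + 1):(n_steps + 1), ] <- -60
  rec <- structure(list(V = cmd, dt = cfg$dt, duration = 100,
                        stimulus = hue_stimulus("none", 0, 0), seed = 1,
                        spikes = rep(list(numeric(0)), cfg$n_cortical),
                        I_lgn = matrix(0, n_steps + 1, cfg$n_cortical),
                        config_digest = "synthetic"),
                   class = "recording")
  colnames(rec$V) <- colnames(rec$I_lgn) <- letters[1:cfg$n_cortical]
  res <- run_with_replay(cfg, hue_stimulus("none", 0, 0), rec, "feedback")
  # clamp tau = Rs * C = 4 us << dt, so tracking within 1 ms is conservative
  after <- res$time > 11
  expect_lt(max(abs(res$V[after, "a"] + 60)), 0.1)
})

test_that("feedback replay without a stimulus reproduces the recorded activity", {
  cmp <- compare_traces(fb_nostim(), green_recording())
  expect_lt(cmp$max_abs_diff_mV, 1)
  shifts <- unlist(cmp$spike_time_diffs_ms)
  expect_lte(max(abs(shifts), 0), ref_config()$dt)
})

test_that("the clamp current recreates the missing LGN input (I_vc matches recorded I_LGN)", {
  fb <- fb_nostim()
  rec <- green_recording()
  for (nm in c("a", "b")) {
    expect_lt(reconstruction_error(fb$I_vc[, nm], rec$I_lgn[, nm]), 0.05)
  }
})

test_that("feedforward and feedback replay are equivalent in the dark", {
  ff <- ff_nostim()
  fb <- fb_nostim()
  cmp <- compare_traces(ff, fb)
  expect_lt(cmp$max_abs_diff_mV, 1)
  expect_identical(lapply(ff$spikes, length), lapply(fb$spikes, length))
  shifts <- unlist(cmp$spike_time_diffs_ms)
  expect_lte(max(abs(shifts), 0), ref_config()$dt)
  # feedforward overwrite is exact by construction
  expect_identical(ff$V, green_recording()$V)
})

test_that("congruent replay injects nothing; incongruent replay reconstructs the missing node", {
  cg <- fb_congruent()
  expect_lte(max(abs(cg$I_vc)), 1)
  expect_identical(classify_nothing_result(cg), "NOTHING_TYPE_II")

  ir <- fb_incongruent()
  expect_identical(n_firing_neurons(ir), 5L)
  expect_gt(max(abs(ir$I_vc[, "a"])), 100)   # missing green node recreated
  expect_lte(max(abs(ir$I_vc[, "b"])), 1)    # red-driven neuron untouched
  expect_identical(classify_nothing_result(ir), "INTERVENTION")
})

test_that("Nothing type I and type II leave identical brain activity", {
  off <- clamp_off_green()
  cg <- fb_congruent()
  expect_identical(classify_nothing_result(off), "NOTHING_TYPE_I")
  expect_lt(max(abs(off$V - cg$V)), 1e-9)
  expect_identical(off$V, green_recording()$V)  # clamp off == plain rerun
})

test_that("clamp charge summarizes interventions and is undefined for feedforward replay", {
  expect_true(all(clamp_charge(clamp_off_green()) == 0))
  expect_true(all(is.na(clamp_charge(ff_nostim()))))
  q_cong <- sum(clamp_charge(fb_congruent()))
  q_incong <- sum(clamp_charge(fb_incongruent()))
  expect_lt(q_cong, 1e-3 * q_incong)
})

test_that("classify_nothing distinguishes the two nothings from intervention", {
  iv <- matrix(0, 10, 5)
  expect_identical(classify_nothing("off", FALSE, iv), "NOTHING_TYPE_I")
  expect_identical(classify_nothing("feedback", TRUE, iv), "NOTHING_TYPE_II")
  iv[5, 3] <- 250
  expect_identical(classify_nothing("feedback", TRUE, iv), "INTERVENTION")
  expect_identical(classify_nothing("feedback", TRUE, iv, tolerance = 300),
                   "NOTHING_TYPE_II")
})

test_that("replay rejects a recording on a mismatched grid", {
  cfg <- ref_config()
  rec <- green_recording()
  bad <- rec
  bad$V <- bad$V[-1, , drop = FALSE]
  expect_error(run_with_replay(cfg, hue_stimulus("green"), bad, "feedback"),
               class = "incompatible_recording")
  cfg2 <- network_config(dt = 0.05)
  expect_error(run_with_replay(cfg2, hue_stimulus("green"), rec, "feedback"),
               class = "incompatible_recording")
})
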