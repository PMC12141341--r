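test_that("the unary incrementer records one tuple per step and appends a 1", {
  spec <- tm_unary_incrementer()
  out <- tm_run_and_record(spec, c("1", "1"))
  expect_identical(nrow(out$record), 3L)       # two 1s scanned + one write
  expect_identical(out$final_tape, c("1", "1", "1"))
  expect_true(out$halted)
  expect_identical(out$record$s, rep("scan", 3))
  expect_identical(out$record$w, c("1", "1", "1"))
})

test_that("a machine starting in a halting state records nothing", {
  spec <- tm_unary_incrementer()
  spec$initial <- "done"
  out <- tm_run_and_record(spec, c("1"))
  expect_identical(nrow(out$record), 0L)
  expect_true(out$halted)
})

test_that("recording requires a positive step budget and a total transition function", {
  spec <- tm_unary_incrementer()
  expect_error(tm_run_and_record(spec, c("1"), max_steps = 0),
               class = "invalid_params")
  broken <- spec
  broken$transitions <- broken$transitions[1, , drop = FALSE]  # no blank rule
  expect_error(tm_run_and_record(broken, c("1")), class = "malformed_spec")
})

test_that("recording a deterministic machine is reproducible bit for bit", {
  fx <- parity_fixture()
  again <- tm_run_and_record(fx$spec, fx$green)
  expect_identical(fx$rec, again)
})

test_that("feedforward replay applies the recorded writes blind to the tape", {
  fx <- parity_fixture()
  on_green <- tm_feedforward_replay(fx$rec$record, fx$green)
  expect_identical(on_green$final_tape, fx$rec$final_tape)
  # same ops land on a different tape and even on an empty tape
  on_red <- tm_feedforward_replay(fx$rec$record, fx$red)
  expect_identical(on_red$ops, fx$rec$record[, c("w", "m")])
  on_empty <- tm_feedforward_replay(fx$rec$record, character(0))
  # positional bookkeeping oracle: replay head positions computed directly
  pos <- 1L
  expected <- character(0)
  for (k in seq_len(nrow(fx$rec$record))) {
    expected[pos] <- fx$rec$record$w[k]
    pos <- pos + if (fx$rec$record$m[k] == "R") 1L else -1L
  }
  expect_identical(on_empty$final_tape[seq_along(expected)], expected)
  expect_true(is.na(on_empty$interventions))
})

test_that("feedback replay monitors on the congruent tape and corrects on incongruent tapes", {
  fx <- parity_fixture()
  cong <- tm_feedback_replay(fx$spec, fx$rec$record, fx$green)
  expect_identical(cong$interventions, 0L)
  expect_identical(cong$final_tape, fx$rec$final_tape)

  incong <- tm_feedback_replay(fx$spec, fx$rec$record, fx$red)
  expect_gt(incong$interventions, 0L)
  # net writes always equal the feedforward result
  ff <- tm_feedforward_replay(fx$rec$record, fx$red)
  expect_identical(incong$final_tape, ff$final_tape)

  # byte-identical across repeated congruent replays
  expect_identical(cong, tm_feedback_replay(fx$spec, fx$rec$record, fx$green))
})

test_that("replay write/move sequences are tape-independent (output equivalence)", {
  fx <- parity_fixture()
  tapes <- list(fx$green, fx$red, c("0"), c("1", "1", "1", "1", "1"),
                character(0))
  ff_ops <- lapply(tapes, function(tp) {
    tm_feedforward_replay(fx$rec$record, tp)$ops
  })
  fb_ops <- lapply(tapes, function(tp) {
    tm_feedback_replay(fx$spec, fx$rec$record, tp)$ops
  })
  for (k in seq_along(tapes)) {
    expect_identical(ff_ops[[k]], fx$rec$record[, c("w", "m")])
    expect_identical(fb_ops[[k]], fx$rec$record[, c("w", "m")])
  }
})

test_that("replay collapses the reachable state set to the recorded path", {
  fx <- parity_fixture()
  free <- reachable_state_set(fx$spec, list(fx$green, fx$red), "free")
  replayed <- reachable_state_set(fx$spec, list(fx$green, fx$red),
                                  "feedback_replay", fx$rec$record)
  # the even-parity branch terminal state is erased by the replay
  expect_true(all(replayed %in% free))
  expect_gt(length(free), length(replayed))
  expect_true("accept_even" %in% setdiff(free, replayed))

  # an ensemble of just the recorded tape reaches no extra states
  free1 <- reachable_state_set(fx$spec, list(fx$green), "free")
  expect_setequal(free1, replayed)

  expect_error(reachable_state_set(fx$spec, list(fx$green),
                                   "feedback_replay"),
               class = "invalid_params")
})

test_that("erasure holds over random tape ensembles containing the recorded tape", {
  fx <- parity_fixture()
  set.seed(99)
  for (r in 1:10) {
    extra <- lapply(1:3, function(i) {
      sample(c("0", "1"), sample(1:6, 1), replace = TRUE)
    })
    ensemble <- c(list(fx$green), extra)
    free <- reachable_state_set(fx$spec, ensemble, "free")
    replayed <- reachable_state_set(fx$spec, ensemble, "feedback_replay",
                                    fx$rec$record)
    expect_lte(length(replayed), length(free))
    expect_true(all(replayed %in% free))
  }
})

test_that("TM specs and head records survive a serialization round trip", {
  fx <- parity_fixture()
  spec_path <- tempfile(fileext = ".json")
  write_tm_spec(fx$spec, spec_path)
  spec2 <- read_tm_spec(spec_path)
  expect_identical(spec2$transitions, fx$spec$transitions)
  expect_identical(spec2$halting, fx$spec$halting)

  rec_path <- tempfile(fileext = ".csv")
  write_head_record(fx$rec$record, rec_path)
  rec2 <- read_head_record(rec_path)
  expect_identical(as.data.frame(unclass(rec2)),
                   as.data.frame(unclass(fx$rec$record)))
  # a replay driven by the deserialized record matches the original
  expect_identical(tm_feedback_replay(fx$spec, rec2, fx$red)$final_tape,
                   tm_feedback_replay(fx$spec, fx$rec$record,
                                      fx$red)$final_tape)
})
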