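#' Record a reference run for later replay
#'
#' Runs the network open loop and stores the per-neuron voltage traces as
#' the command-voltage prescription, together with full provenance (seed,
#' step size, stimulus, configuration digest).  Re-recording with the same
#' inputs reproduces the traces bit for bit.
#'
#' @inheritParams run_simulation
#' @return An object of class `recording`.
#' @export
record_reference_run <- function(config, stimulus = hue_stimulus(),
                                 duration = 500, seed = 1) {
  res <- run_simulation(config, stimulus, duration, seed)
  rec <- list(V = res$V, dt = res$dt, duration = duration,
              stimulus = stimulus, seed = seed,
              spikes = res$spikes, I_lgn = res$I_lgn,
              config_digest = res$config_digest)
  class(rec) <- "recording"
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s stimulus, %.0f ms, dt = %g ms, seed = %s, %d neurons\n",
              x$stimulus$hue, x$duration, x$dt, x$seed, ncol(x$V)))
  invisible(x)
}

#' Voltage-clamp parameters for feedback replay
#'
#' The clamp injects `I_vc = (V_cmd - V_m) / series_resistance` into each
#' cortical neuron.  A small series resistance makes the correction far
#' faster than the membrane time constant; the clamp term is solved
#' implicitly inside the voltage update, so stiffness does not limit the
#' step size.  The clamp time constant `series_resistance * capacitance`
#' must stay within 10 integration steps for the tracking guarantees to
#' hold.
#'
#' @param series_resistance Clamp series resistance (MOhm).
#' @param enabled Whether the amplifier is switched on.
#' @return An object of class `clamp_params`.
#' @export
clamp_params <- function(series_resistance = 0.02, enabled = TRUE) {
  if (series_resistance <= 0) {
    rn_stop("series_resistance must be > 0", "invalid_params")
  }
  p <- list(series_resistance = series_resistance, enabled = enabled)
  class(p) <- "clamp_params"
  p
}

#' Ideal clamp current for a voltage deviation
#'
#' @param V_cmd Command voltage (mV).
#' @param V_m Measured membrane voltage (mV).
#' @param series_resistance Series resistance (MOhm).
#' @return Commanded current (pA), positive depolarizing.
#' @export
feedback_clamp_current <- function(V_cmd, V_m, series_resistance) {
  if (series_resistance <= 0) {
    rn_stop("series_resistance must be > 0", "invalid_params")
  }
  1000 * (V_cmd - V_m) / series_resistance
}

#' Replay a recording into the network
#'
#' Three modes:
#' \describe{
#'   \item{off}{Ignore the recording; identical to [run_simulation()] with
#'     the recording's seed.}
#'   \item{feedforward}{Overwrite every cortical neuron's voltage with the
#'     recorded trace at each step, ignoring ongoing activity.  Synapses
#'     are still driven by spikes detected on the (overwritten) voltages,
#'     but those inputs have no effect on the clamped voltages.}
#'   \item{feedback}{Attach a voltage clamp to every cortical neuron with
#'     the recorded trace as command voltage.  Corrective current flows
#'     only where ongoing activity deviates from the command; its trace is
#'     stored per neuron in `I_vc`.}
#' }
#' The stimulus (if any) drives the LGN streams with the *recording's*
#' seed, so a stimulus with the same hue as the recording is congruent:
#' the afferent drive is identical and the clamp has nothing to correct.
#'
#' @param config `network_config`; must match the recording's digest.
#' @param stimulus `hue_stimulus` presented during the replay
#'   (`hue_stimulus("none", duration = 0)` for replay in the dark).
#' @param recording `recording` holding the command voltages.
#' @param mode `"off"`, `"feedforward"` or `"feedback"`.
#' @param clamp `clamp_params` (feedback mode).
#' @return A `sim_result`; in feedback mode `I_vc` holds the clamp
#'   currents actually injected.
#' @export
run_with_replay <- function(config, stimulus, recording,
                            mode = c("feedback", "feedforward", "off"),
                            clamp = clamp_params()) {
  mode <- match.arg(mode)
  n_steps <- round(recording$duration / recording$dt)
  if (abs(recording$dt - config$dt) > 1e-12 ||
      nrow(recording$V) != n_steps + 1 ||
      ncol(recording$V) != config$n_cortical) {
    rn_stop("incompatible recording: time grid or neuron count mismatch",
            "incompatible_recording")
  }
  if (mode == "off") {
    return(run_simulation(config, stimulus, recording$duration,
                          recording$seed))
  }
  if (mode == "feedback") {
    tau_clamp <- clamp$series_resistance * config$neuron_params$capacitance / 1000
    if (!clamp$enabled) {
      rn_stop("feedback replay requires an enabled clamp", "invalid_params")
    }
    if (tau_clamp > 10 * config$dt) {
      rn_stop("clamp time constant exceeds 10 integration steps",
              "invalid_params")
    }
  }
  active <- hue_to_lgn(stimulus$hue)
  trains <- lapply(seq_along(config$lgn_targets), function(j) {
    if (j %in% active && stimulus$duration > 0) {
      generate_lgn_spike_train(config$lgn, j, recording$seed,
                               stimulus$onset, stimulus$duration)
    } else numeric(0)
  })
  mode_code <- c(feedforward = 1L, feedback = 2L)[[mode]]
  raw <- run_network_core(config, trains, recording$duration,
                          mode = mode_code,
                          command = unname(recording$V),
                          series_resistance = clamp$series_resistance)
  make_sim_result(raw, config, stimulus, recording$duration,
                  recording$seed, mode = mode,
                  clamp_enabled = (mode == "feedback"))
}

#' Total rectified clamp charge per neuron
#'
#' Integrates `|I_vc|` over the run for each neuron: a scalar summary of
#' how much the clamp intervened.  Zero on every neuron means the clamp
#' (or open loop) injected nothing.
#'
#' @param result `sim_result`.
#' @return Named numeric vector of charges (pC); `NA` for a feedforward
#'   run, where no clamp current exists.
#' @export
clamp_charge <- function(result) {
  labels <- colnames(result$V)
  if (identical(result$mode, "feedforward")) {
    return(structure(rep(NA_real_, ncol(result$V)), names = labels))
  }
  q <- colSums(abs(result$I_vc)) * result$dt / 1000  # pA*ms -> pC
  structure(q, names = labels)
}

#' Classify how a replay run "did nothing" (or intervened)
#'
#' \describe{
#'   \item{NOTHING_TYPE_I}{The clamp hardware was off: no current and no
#'     potential current.}
#'   \item{NOTHING_TYPE_II}{The clamp was on but never injected more than
#'     `tolerance` on any neuron: ongoing activity already matched the
#'     command voltage, yet every alternative trajectory was pre-empted.}
#'   \item{INTERVENTION}{The clamp injected appreciable current.}
#' }
#'
#' @param mode Replay mode of the run.
#' @param clamp_enabled Whether the amplifier was on.
#' @param I_vc Matrix of clamp-current traces (time x neuron, pA).
#' @param tolerance Current magnitude regarded as "nothing" (pA).  The
#'   default 1 pA sits far above floating-point noise and more than two
#'   orders of magnitude below the synaptic currents in this network.
#' @return One of `"NOTHING_TYPE_I"`, `"NOTHING_TYPE_II"`,
#'   `"INTERVENTION"`.
#' @export
classify_nothing <- function(mode, clamp_enabled, I_vc, tolerance = 1) {
  if (identical(mode, "off") || !isTRUE(clamp_enabled)) {
    return("NOTHING_TYPE_I")
  }
  if (max(abs(I_vc)) <= tolerance) "NOTHING_TYPE_II" else "INTERVENTION"
}

#' @rdname classify_nothing
#' @param result `sim_result` from which mode, clamp state and `I_vc` are
#'   taken.
#' @export
classify_nothing_result <- function(result, tolerance = 1) {
  classify_nothing(result$mode, result$clamp_enabled, result$I_vc, tolerance)
}
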