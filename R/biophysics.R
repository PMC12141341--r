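#' Membrane parameters for a single-compartment cortical neuron
#'
#' Defaults describe a regular-spiking cortical cell reduced to one
#' compartment with Na+, K+ and leak channels.  The leak conductance of
#' 20 nS sets the input resistance to 50 MOhm, and with 200 pF capacitance
#' the membrane time constant is 10 ms.  `threshold_shift` positions the
#' voltage dependence of the gating kinetics so that the spike threshold
#' sits near -55 mV.
#'
#' @param capacitance Membrane capacitance (pF).
#' @param leak_conductance Leak conductance (nS); its reciprocal is the
#'   passive input resistance in GOhm (20 nS gives 50 MOhm).
#' @param leak_reversal Leak reversal / resting potential (mV).
#' @param na_max_conductance Maximal Na+ conductance (nS).
#' @param na_reversal Na+ reversal (mV).
#' @param k_max_conductance Maximal delayed-rectifier K+ conductance (nS).
#' @param k_reversal K+ reversal (mV).
#' @param threshold_shift Voltage offset of the gating rate functions (mV);
#'   more negative values lower the spike threshold.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(capacitance = 200,
                          leak_conductance = 20,
                          leak_reversal = -70,
                          na_max_conductance = 6000,
                          na_reversal = 50,
                          k_max_conductance = 1200,
                          k_reversal = -77,
                          threshold_shift = -64) {
  if (capacitance <= 0) rn_stop("capacitance must be > 0", "invalid_params")
  for (g in c(leak_conductance, na_max_conductance, k_max_conductance)) {
    if (g < 0) rn_stop("conductances must be >= 0", "invalid_params")
  }
  p <- list(capacitance = capacitance,
            leak_conductance = leak_conductance,
            leak_reversal = leak_reversal,
            na_max_conductance = na_max_conductance,
            na_reversal = na_reversal,
            k_max_conductance = k_max_conductance,
            k_reversal = k_reversal,
            threshold_shift = threshold_shift)
  class(p) <- "neuron_params"
  p
}

#' Neuron state: membrane voltage and HH gate activations
#'
#' Gates default to their steady-state values at the given voltage, so
#' `neuron_state(V = params$leak_reversal)` is (numerically) the resting
#' fixed point of the dynamics.
#'
#' @param V Membrane voltage (mV).
#' @param m,h,n Gate activations in \[0, 1\]; `NULL` means steady state at `V`.
#' @param params `neuron_params` supplying the kinetics offset.
#' @return An object of class `neuron_state` (named numeric of V, m, h, n).
#' @export
neuron_state <- function(V = -70, m = NULL, h = NULL, n = NULL,
                         params = neuron_params()) {
  if (!is.finite(V)) rn_stop("V must be finite", "invalid_state")
  g <- hh_steady_gates_cpp(V, params$threshold_shift)
  m <- if (is.null(m)) g[["m"]] else m
  h <- if (is.null(h)) g[["h"]] else h
  n <- if (is.null(n)) g[["n"]] else n
  gates <- c(m, h, n)
  if (any(gates < 0 | gates > 1)) {
    rn_stop("gate activations must lie in [0, 1]", "invalid_state")
  }
  s <- c(V = V, m = m, h = h, n = n)
  class(s) <- "neuron_state"
  s
}

#' Advance a neuron by one integration step
#'
#' Gates are updated by exponential Euler at the pre-step voltage; the
#' voltage update is semi-implicit (conductances multiply the end-of-step
#' voltage), which keeps the step stable even under the very stiff
#' clamp conductance used for feedback replay.
#'
#' @param state `neuron_state`.
#' @param params `neuron_params`.
#' @param input_current Injected current (pA), positive depolarizing.
#' @param dt Step size (ms).
#' @return Updated `neuron_state`.
#' @export
step_neuron <- function(state, params, input_current, dt) {
  if (dt <= 0) rn_stop("dt must be > 0", "invalid_params")
  if (!all(is.finite(unclass(state)))) {
    bad <- names(unclass(state))[!is.finite(unclass(state))][1]
    rn_stop(sprintf("integration failure: state variable '%s' non-finite", bad),
            "integration_failure")
  }
  out <- hh_step_cpp(unclass(state), unclass(params), input_current, dt)
  if (!all(is.finite(out))) {
    rn_stop("integration failure: V non-finite after step",
            "integration_failure")
  }
  class(out) <- "neuron_state"
  out
}

#' Simulate one neuron against a current trace
#'
#' @param params `neuron_params`.
#' @param input_current Vector of injected current (pA), one value per step.
#' @param dt Step size (ms).
#' @param init Initial `neuron_state`; defaults to rest.
#' @param spike_threshold,spike_refractory Spike detection settings
#'   (mV upward crossing; minimum separation in ms).
#' @return List with traces `V`, `m`, `h`, `n` (length `length(input_current)
#'   + 1`), detected `spikes` (ms) and the time grid `time`.
#' @export
simulate_neuron <- function(params, input_current, dt = 0.025,
                            init = NULL, spike_threshold = 0,
                            spike_refractory = 2) {
  if (dt <= 0) rn_stop("dt must be > 0", "invalid_params")
  if (is.null(init)) init <- neuron_state(params$leak_reversal, params = params)
  out <- simulate_neuron_cpp(unclass(params), unclass(init),
                             as.numeric(input_current), dt,
                             spike_threshold, spike_refractory)
  out$time <- seq(0, by = dt, length.out = length(out$V))
  out
}

#' Measure input resistance with a hyperpolarizing current probe
#'
#' Injects a small negative current step from rest, waits `settle_time`,
#' and returns the steady-state voltage deflection divided by the probe
#' amplitude.  The probe must be hyperpolarizing and small so the
#' measurement stays in the passive regime; a spike evoked during the
#' probe invalidates it.
#'
#' @param params `neuron_params`.
#' @param probe_current Probe amplitude (pA), `<= 0` and `|I| <= 50`.
#' @param settle_time Time allowed to reach steady state (ms).
#' @param dt Step size (ms).
#' @return Input resistance in MOhm.
#' @export
measure_input_resistance <- function(params, probe_current = -20,
                                     settle_time = 500, dt = 0.025) {
  if (probe_current == 0 || probe_current > 0 || abs(probe_current) > 50) {
    rn_stop("invalid probe: current must be hyperpolarizing, 0 < |I| <= 50 pA",
            "invalid_probe")
  }
  n_steps <- round(settle_time / dt)
  trace <- simulate_neuron(params, rep(probe_current, n_steps), dt = dt)
  if (length(trace$spikes) > 0 || max(trace$V) > 0) {
    rn_stop("invalid probe: spike evoked during measurement", "invalid_probe")
  }
  # average over the final 5% of the probe to suppress residual relaxation
  tail_idx <- seq(floor(0.95 * n_steps), n_steps) + 1
  dV <- mean(trace$V[tail_idx]) - params$leak_reversal
  1000 * dV / probe_current  # mV / nA = MOhm
}

#' Synaptic conductance parameters
#'
#' The conductance transient is a difference of exponentials normalized so
#' that an event at full strength peaks at exactly `peak_conductance`.
#' `rise_time` is the time from event onset to the conductance peak; the
#' internal rise constant is solved from it given `decay_tau`, so both
#' printed kinetic numbers (time-to-peak and decay constant) are directly
#' recoverable from a simulated transient.
#'
#' Cortical synapses depress: after each presynaptic spike the strength is
#' multiplied by `depression_factor` and then recovers toward 1 with
#' first-order kinetics (`recovery_tau`).  LGN afferents use
#' `depressing = FALSE`.
#'
#' @param peak_conductance Peak conductance of one full-strength event (nS).
#' @param rise_time Time from event to conductance peak (ms).
#' @param decay_tau Decay time constant of the transient (ms).
#' @param reversal Synaptic reversal potential (mV).
#' @param depressing Whether the synapse shows short-term depression.
#' @param depression_factor Multiplicative strength factor per spike.
#' @param recovery_tau Recovery time constant of the strength variable (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(peak_conductance = 5,
                           rise_time = 2,
                           decay_tau = 10,
                           reversal = 0,
                           depressing = TRUE,
                           depression_factor = 0.5,
                           recovery_tau = 1000) {
  if (peak_conductance <= 0) rn_stop("peak_conductance must be > 0",
                                     "invalid_params")
  if (depression_factor <= 0 || depression_factor > 1) {
    rn_stop("depression_factor must lie in (0, 1]", "invalid_params")
  }
  if (rise_time >= decay_tau) {
    rn_stop("rise_time must be smaller than decay_tau", "invalid_params")
  }
  # solve tau_rise so the double-exponential peaks at rise_time
  t_peak <- function(tr) tr * decay_tau / (decay_tau - tr) * log(decay_tau / tr)
  tau_rise <- stats::uniroot(function(tr) t_peak(tr) - rise_time,
                             lower = 1e-6, upper = decay_tau * (1 - 1e-9),
                             tol = 1e-12)$root
  peak_val <- exp(-rise_time / decay_tau) - exp(-rise_time / tau_rise)
  p <- list(peak_conductance = peak_conductance,
            rise_time = rise_time,
            decay_tau = decay_tau,
            tau_rise = tau_rise,
            reversal = reversal,
            depressing = depressing,
            depression_factor = depression_factor,
            recovery_tau = recovery_tau,
            peak_norm = 1 / peak_val)
  class(p) <- "synapse_params"
  p
}

#' Synapse state
#'
#' `rise_component` and `decay_component` are the two exponentials of the
#' conductance transient (instantaneous conductance = decay - rise, clipped
#' at 0); `strength` is the depression variable in (0, 1].
#'
#' @param rise_component,decay_component Transient state (nS scale).
#' @param strength Depression variable.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(rise_component = 0, decay_component = 0,
                          strength = 1) {
  if (strength <= 0 || strength > 1) {
    rn_stop("strength must lie in (0, 1]", "invalid_state")
  }
  s <- list(rise_component = rise_component,
            decay_component = decay_component,
            strength = strength)
  class(s) <- "synapse_state"
  s
}

#' Register a presynaptic spike at a synapse
#'
#' Increments the conductance transient with amplitude
#' `strength * peak_conductance`; if the synapse depresses, the strength is
#' then multiplied by `depression_factor` (for the reference cortical
#' synapse: dropped to 50% of its value).
#'
#' @param state `synapse_state`.
#' @param params `synapse_params`.
#' @return Updated `synapse_state`.
#' @export
synapse_event <- function(state, params) {
  amp <- state$strength * params$peak_conductance * params$peak_norm
  state$rise_component <- state$rise_component + amp
  state$decay_component <- state$decay_component + amp
  if (params$depressing) {
    state$strength <- state$strength * params$depression_factor
  }
  state
}

#' Advance a synapse state by one time step
#'
#' Both transient components decay exponentially with their time constants;
#' the strength relaxes toward 1 as ds/dt = (1 - s) / recovery_tau.
#'
#' @param state `synapse_state`.
#' @param params `synapse_params`.
#' @param dt Step size (ms).
#' @return Updated `synapse_state`.
#' @export
synapse_step <- function(state, params, dt) {
  if (dt <= 0) rn_stop("dt must be > 0", "invalid_params")
  state$rise_component <- state$rise_component * exp(-dt / params$tau_rise)
  state$decay_component <- state$decay_component * exp(-dt / params$decay_tau)
  state$strength <- 1 - (1 - state$strength) * exp(-dt / params$recovery_tau)
  state
}

#' Instantaneous synaptic conductance of a synapse state
#'
#' @param state `synapse_state`.
#' @return Conductance (nS), never negative.
#' @export
synapse_conductance <- function(state) {
  max(state$decay_component - state$rise_component, 0)
}

#' Synaptic current into the postsynaptic neuron
#'
#' @param state `synapse_state`.
#' @param params `synapse_params`.
#' @param V_post Postsynaptic membrane voltage (mV).
#' @return Current (pA), positive depolarizing.
#' @export
synaptic_current <- function(state, params, V_post) {
  synapse_conductance(state) * (params$reversal - V_post)
}
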