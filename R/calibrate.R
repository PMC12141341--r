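#' Simulate the conductance transient of a single synaptic event
#'
#' Steps a fresh synapse to the event, fires it once at full strength, and
#' integrates the transient on the simulation grid.
#'
#' @param params `synapse_params`.
#' @param duration Window after the event (ms).
#' @param dt Step size (ms).
#' @return `data.frame` with `time` (ms since the event) and `g` (nS).
#' @export
synapse_transient <- function(params, duration = 60, dt = 0.025) {
  st <- synapse_event(synapse_state(), params)
  n <- round(duration / dt)
  g <- numeric(n + 1)
  g[1] <- synapse_conductance(st)
  for (k in seq_len(n)) {
    st <- synapse_step(st, params, dt)
    g[k + 1] <- synapse_conductance(st)
  }
  data.frame(time = seq(0, by = dt, length.out = n + 1), g = g)
}

#' Calibration measurements of the reference model
#'
#' Recovers every printed model parameter as a *measured* quantity:
#' \describe{
#'   \item{input_resistance_MOhm}{Hyperpolarizing-probe measurement on one
#'     neuron (target 50 MOhm).}
#'   \item{syn_decay_tau_ms}{Log-linear fit to the conductance tail after a
#'     single event (target 10 ms).}
#'   \item{syn_rise_time_ms}{Time from event to peak conductance
#'     (target 2 ms).}
#'   \item{syn_peak_nS}{Peak conductance at full strength (target 5 nS).}
#'   \item{depression_after_spike}{Strength immediately after one
#'     presynaptic event (target 0.5).}
#'   \item{recovery_tau_ms}{Log-linear fit of the strength recovery
#'     (target 1000 ms).}
#'   \item{n_cortical, n_lgn_nodes}{Reference topology counts.}
#' }
#'
#' @param cfg `run_config`.
#' @return Named list of measured values.
#' @export
calibrate <- function(cfg = run_config()) {
  net <- as_network_config(cfg)
  np <- net$neuron_params
  sp <- net$cortical_synapse

  rin <- measure_input_resistance(np, probe_current = -20,
                                  settle_time = 500, dt = cfg$dt)

  tr <- synapse_transient(sp, duration = 80, dt = cfg$dt)
  peak_idx <- which.max(tr$g)
  rise_time <- tr$time[peak_idx]
  peak_g <- tr$g[peak_idx]
  # fit the decay tail well clear of the rise component
  tail <- tr[tr$time >= rise_time + 5 & tr$g > 0, ]
  fit <- lm(log(g) ~ time, data = tail)
  decay_tau <- -1 / coef(fit)[["time"]]

  st <- synapse_event(synapse_state(), sp)
  depression_after <- st$strength

  # strength recovery from the depressed value, sampled every ms
  n_ms <- 3000
  s_trace <- numeric(n_ms + 1)
  s_trace[1] <- st$strength
  st_r <- st
  for (k in seq_len(n_ms)) {
    st_r <- synapse_step(st_r, sp, 1)
    s_trace[k + 1] <- st_r$strength
  }
  rec <- data.frame(time = 0:n_ms, deficit = 1 - s_trace)
  rec <- rec[rec$deficit > 1e-12, ]
  rfit <- lm(log(deficit) ~ time, data = rec)
  recovery_tau <- -1 / coef(rfit)[["time"]]

  list(input_resistance_MOhm = rin,
       syn_decay_tau_ms = decay_tau,
       syn_rise_time_ms = rise_time,
       syn_peak_nS = peak_g,
       depression_after_spike = depression_after,
       recovery_tau_ms = recovery_tau,
       n_cortical = net$n_cortical,
       n_lgn_nodes = length(net$lgn_targets))
}
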