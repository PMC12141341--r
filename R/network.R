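CORTICAL_LABELS <- letters[1:26]

#' Cyclic cortical topology
#'
#' Neuron k receives from the `fan_in` immediately preceding neurons in
#' cyclic order: with five neurons and fan-in 3, neuron d listens to a, b
#' and c, and neuron a wraps around to c, d, e.
#'
#' @param n_cortical Number of cortical neurons.
#' @param fan_in Number of presynaptic neurons per cell; must be smaller
#'   than `n_cortical`.
#' @return Named list mapping each neuron label to the labels of its
#'   presynaptic set.
#' @export
build_cyclic_network <- function(n_cortical = 5, fan_in = 3) {
  if (fan_in <= 0 || fan_in >= n_cortical) {
    rn_stop("invalid topology: need 0 < fan_in < n_cortical",
            "invalid_topology")
  }
  labels <- CORTICAL_LABELS[seq_len(n_cortical)]
  pre <- lapply(seq_len(n_cortical), function(k) {
    idx <- ((k - 1 - seq_len(fan_in)) %% n_cortical) + 1
    sort(labels[idx])
  })
  names(pre) <- labels
  pre
}

# presynaptic map -> E x 2 matrix of 0-based (pre, post) indices
topology_edges <- function(pre_map) {
  labels <- names(pre_map)
  edges <- do.call(rbind, lapply(seq_along(pre_map), function(k) {
    cbind(match(pre_map[[k]], labels) - 1L, k - 1L)
  }))
  storage.mode(edges) <- "integer"
  edges
}

#' LGN input-node parameters
#'
#' Each LGN node emits a random spike train while its hue channel is
#' active: renewal spiking with a refractory dead time followed by an
#' exponential interval, scaled so the mean rate equals `rate`.
#'
#' @param rate Mean firing rate while active (spikes/s).
#' @param refractory Dead time after each spike (ms).
#' @return An object of class `lgn_params`.
#' @export
lgn_params <- function(rate = 100, refractory = 2) {
  if (rate <= 0) rn_stop("rate must be > 0", "invalid_params")
  if (refractory < 0 || refractory >= 1000 / rate) {
    rn_stop("refractory must lie in [0, mean ISI)", "invalid_params")
  }
  p <- list(rate = rate, refractory = refractory)
  class(p) <- "lgn_params"
  p
}

#' Map a stimulus hue to the set of active LGN nodes
#'
#' Green light activates both LGN nodes; red activates only the node that
#' drives neuron b; blue only the node that drives neuron a; no stimulus
#' activates neither.
#'
#' @param hue One of `"green"`, `"red"`, `"blue"`, `"none"`.
#' @return Integer vector of active node ids (1-based; node 1 targets
#'   neuron a, node 2 targets neuron b).
#' @export
hue_to_lgn <- function(hue) {
  switch(as.character(hue),
         green = c(1L, 2L),
         red = 2L,
         blue = 1L,
         none = integer(0),
         rn_stop(sprintf("invalid stimulus hue '%s'", hue),
                 "invalid_stimulus"))
}

#' Hue stimulus descriptor
#'
#' @param hue Stimulus hue (see [hue_to_lgn()]).
#' @param onset Stimulus onset (ms).
#' @param duration Stimulus duration (ms).
#' @return An object of class `hue_stimulus`.
#' @export
hue_stimulus <- function(hue = "green", onset = 100, duration = 300) {
  hue_to_lgn(hue)  # validates
  if (onset < 0 || duration < 0) {
    rn_stop("onset and duration must be >= 0", "invalid_stimulus")
  }
  s <- list(hue = hue, onset = onset, duration = duration)
  class(s) <- "hue_stimulus"
  s
}

#' Generate the seeded spike train of one LGN node
#'
#' The train is a pure function of `(run_seed, node_id)`: it does not
#' depend on the hue or on which other nodes are active, so a node that is
#' active under two different stimuli emits the identical train.  This
#' seeding contract is what makes a "congruent" stimulus during replay
#' well defined.
#'
#' @param params `lgn_params`.
#' @param node_id LGN node id (1-based).
#' @param run_seed Integer seed of the simulation run.
#' @param onset,duration Active window (ms).
#' @return Numeric vector of spike times (ms) inside the window.
#' @export
generate_lgn_spike_train <- function(params, node_id, run_seed,
                                     onset = 100, duration = 300) {
  if (duration < 0) rn_stop("duration must be >= 0", "invalid_stimulus")
  if (duration == 0) return(numeric(0))
  stream_seed <- (as.integer(run_seed) %% 100003L) * 20011L + as.integer(node_id)
  exp_mean <- 1000 / params$rate - params$refractory  # ms
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(stream_seed)
  t <- onset
  out <- numeric(0)
  # first interval has no preceding spike, so no dead time
  t <- t + rexp(1, rate = 1 / exp_mean)
  while (t < onset + duration) {
    out <- c(out, t)
    t <- t + params$refractory + rexp(1, rate = 1 / exp_mean)
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Full network configuration
#'
#' @param n_cortical Number of cortical neurons.
#' @param fan_in Presynaptic fan-in per cortical neuron.
#' @param neuron_params `neuron_params` shared by all cortical cells.
#' @param cortical_synapse `synapse_params` for recurrent connections
#'   (depressing).
#' @param lgn_synapse `synapse_params` for LGN afferents (non-depressing).
#' @param lgn_targets Integer vector: cortical index targeted by each LGN
#'   node (default node 1 -> a, node 2 -> b); must be injective.
#' @param lgn `lgn_params` for the input spike trains.
#' @param synaptic_delay Conduction + synaptic delay for every connection
#'   (ms).
#' @param dt Integration step (ms).
#' @param spike_threshold,spike_refractory Spike detection settings (mV, ms).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_cortical = 5, fan_in = 3,
                           neuron_params = replaynet::neuron_params(),
                           cortical_synapse = synapse_params(depressing = TRUE),
                           lgn_synapse = synapse_params(depressing = FALSE),
                           lgn_targets = c(1L, 2L),
                           lgn = lgn_params(),
                           synaptic_delay = 1,
                           dt = 0.025,
                           spike_threshold = 0,
                           spike_refractory = 2) {
  if (anyDuplicated(lgn_targets)) {
    rn_stop("lgn_targets must be injective", "invalid_topology")
  }
  if (any(lgn_targets < 1 | lgn_targets > n_cortical)) {
    rn_stop("lgn_targets out of range", "invalid_topology")
  }
  topology <- build_cyclic_network(n_cortical, fan_in)  # validates fan_in
  cfg <- list(n_cortical = n_cortical, fan_in = fan_in,
              neuron_params = neuron_params,
              cortical_synapse = cortical_synapse,
              lgn_synapse = lgn_synapse,
              lgn_targets = as.integer(lgn_targets),
              lgn = lgn,
              synaptic_delay = synaptic_delay,
              dt = dt,
              spike_threshold = spike_threshold,
              spike_refractory = spike_refractory,
              topology = topology)
  class(cfg) <- "network_config"
  cfg
}

#' Run an open-loop simulation of the network
#'
#' Wires the cyclic cortical network, draws the LGN spike trains for the
#' active nodes of the stimulus, and integrates the coupled
#' Hodgkin-Huxley/synapse system.  Spikes detected on each presynaptic
#' voltage trigger conductance events at the targets after the synaptic
#' delay.  The run is deterministic given `(config, stimulus, seed, dt)`.
#'
#' @param config `network_config`.
#' @param stimulus `hue_stimulus`.
#' @param duration Total simulated time (ms); must cover the stimulus.
#' @param seed Integer seed for the LGN spike streams.
#' @return An object of class `sim_result` with the time grid, per-neuron
#'   voltage traces `V`, clamp-current traces `I_vc` (all zero in open
#'   loop), LGN-current traces `I_lgn`, spike times, and provenance.
#' @export
run_simulation <- function(config, stimulus = hue_stimulus(),
                           duration = 500, seed = 1) {
  if (duration < stimulus$onset + stimulus$duration) {
    rn_stop("duration must cover the stimulus window", "invalid_stimulus")
  }
  active <- hue_to_lgn(stimulus$hue)
  trains <- lapply(seq_along(config$lgn_targets), function(j) {
    if (j %in% active) {
      generate_lgn_spike_train(config$lgn, j, seed,
                               stimulus$onset, stimulus$duration)
    } else numeric(0)
  })
  raw <- run_network_core(config, trains, duration, mode = 0L,
                          command = matrix(0, 0, 0), series_resistance = 1)
  make_sim_result(raw, config, stimulus, duration, seed,
                  mode = "off", clamp_enabled = FALSE)
}

# shared driver for open-loop and replay runs
run_network_core <- function(config, trains, duration, mode, command,
                             series_resistance) {
  n_steps <- round(duration / config$dt)
  simulate_network_cpp(
    n_steps = as.integer(n_steps), dt = config$dt,
    neuron = unclass(config$neuron_params),
    edges = topology_edges(config$topology),
    syn_cortical = unclass(config$cortical_synapse),
    syn_lgn = unclass(config$lgn_synapse),
    lgn_target = config$lgn_targets - 1L,
    lgn_spikes = trains,
    delay_ms = config$synaptic_delay,
    mode = as.integer(mode),
    command = command,
    series_resistance = series_resistance,
    spike_threshold = config$spike_threshold,
    spike_refractory = config$spike_refractory)
}

make_sim_result <- function(raw, config, stimulus, duration, seed,
                            mode, clamp_enabled) {
  labels <- CORTICAL_LABELS[seq_len(config$n_cortical)]
  colnames(raw$V) <- colnames(raw$I_vc) <- colnames(raw$I_lgn) <- labels
  names(raw$spikes) <- labels
  res <- list(time = seq(0, by = config$dt, length.out = nrow(raw$V)),
              V = raw$V, I_vc = raw$I_vc, I_lgn = raw$I_lgn,
              spikes = raw$spikes,
              dt = config$dt, duration = duration, seed = as.integer(seed),
              stimulus = stimulus, mode = mode,
              clamp_enabled = clamp_enabled,
              config_digest = config_digest(config))
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  counts <- vapply(x$spikes, length, integer(1))
  cat(sprintf("<sim_result> %s stimulus, %.0f ms, dt = %g ms, seed = %s\n",
              x$stimulus$hue, x$duration, x$dt, x$seed))
  cat(sprintf("  replay mode: %s%s\n", x$mode,
              if (x$clamp_enabled) " (clamp on)" else ""))
  cat("  spikes per neuron:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}

#' Detect spikes on a voltage trace
#'
#' One event per upward threshold crossing, with a minimum separation so a
#' noisy double-crossing during a single action potential is not counted
#' twice.
#'
#' @param trace Voltage trace (mV).
#' @param threshold Crossing threshold (mV); must sit above rest.
#' @param dt Sample interval (ms).
#' @param min_separation Minimum time between events (ms).
#' @return Spike times (ms), where time 0 is the first sample.
#' @export
detect_spikes <- function(trace, threshold = 0, dt = 0.025,
                          min_separation = 2) {
  n <- length(trace)
  if (n < 2) return(numeric(0))
  up <- which(trace[-n] < threshold & trace[-1] >= threshold)
  times <- up * dt  # time of the sample that crossed
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= min_separation) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Count of neurons that fired at least one spike
#'
#' @param result `sim_result`.
#' @return Integer count.
#' @export
n_firing_neurons <- function(result) {
  sum(vapply(result$spikes, function(s) length(s) > 0, logical(1)))
}
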