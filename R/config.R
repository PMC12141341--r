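RUN_CONFIG_FIELDS <- c(
  "n_cortical", "fan_in", "lgn_targets", "synaptic_delay", "dt",
  "spike_threshold", "spike_refractory",
  "capacitance", "leak_conductance", "leak_reversal",
  "na_max_conductance", "na_reversal", "k_max_conductance", "k_reversal",
  "threshold_shift",
  "syn_peak_conductance", "syn_rise_time", "syn_decay_tau", "syn_reversal",
  "depression_factor", "recovery_tau",
  "lgn_rate", "lgn_refractory",
  "series_resistance",
  "stimulus_onset", "stimulus_duration", "duration",
  "seed", "out_dir")

#' Reference run configuration
#'
#' A flat, human-editable document holding every tunable of the model with
#' the reference profile as defaults: five cortical neurons with fan-in 3,
#' 5 nS synapses peaking 2 ms after the presynaptic spike and decaying
#' with 10 ms, cortical depression to 50% per spike recovering with 1 s,
#' a 50 MOhm input resistance target, 100 spikes/s LGN drive, and a
#' 0.02 MOhm clamp series resistance.  Values not fixed by the model
#' description (timing, rates, clamp stiffness) are documented design
#' choices; see the methods vignette.
#'
#' @param ... Overrides of the reference fields (unknown names are
#'   rejected).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_cortical = 5L, fan_in = 3L, lgn_targets = c(1L, 2L),
    synaptic_delay = 1, dt = 0.025,
    spike_threshold = 0, spike_refractory = 2,
    capacitance = 200, leak_conductance = 20, leak_reversal = -70,
    na_max_conductance = 6000, na_reversal = 50,
    k_max_conductance = 1200, k_reversal = -77, threshold_shift = -64,
    syn_peak_conductance = 5, syn_rise_time = 2, syn_decay_tau = 10,
    syn_reversal = 0, depression_factor = 0.5, recovery_tau = 1000,
    lgn_rate = 100, lgn_refractory = 2,
    series_resistance = 0.02,
    stimulus_onset = 100, stimulus_duration = 300, duration = 500,
    seed = 1L, out_dir = ".")
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) ||
                                any(names(overrides) == ""))) {
    rn_stop("all overrides must be named", "invalid_config")
  }
  unknown <- setdiff(names(overrides), RUN_CONFIG_FIELDS)
  if (length(unknown) > 0) {
    rn_stop(sprintf("unknown config field(s): %s",
                    paste(unknown, collapse = ", ")), "invalid_config")
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  chk <- function(ok, field, rule) {
    if (!ok) rn_stop(sprintf("config field '%s' violates: %s", field, rule),
                     "invalid_config")
  }
  chk(cfg$n_cortical >= 2, "n_cortical", "must be >= 2")
  chk(cfg$fan_in > 0 && cfg$fan_in < cfg$n_cortical, "fan_in",
      "must satisfy 0 < fan_in < n_cortical")
  chk(cfg$syn_peak_conductance > 0, "syn_peak_conductance", "must be > 0")
  chk(cfg$syn_rise_time > 0 && cfg$syn_rise_time < cfg$syn_decay_tau,
      "syn_rise_time", "must satisfy 0 < rise < decay_tau")
  chk(cfg$depression_factor > 0 && cfg$depression_factor <= 1,
      "depression_factor", "must lie in (0, 1]")
  chk(cfg$recovery_tau > 0, "recovery_tau", "must be > 0")
  chk(cfg$capacitance > 0, "capacitance", "must be > 0")
  chk(cfg$leak_conductance > 0, "leak_conductance", "must be > 0")
  chk(cfg$lgn_rate > 0, "lgn_rate", "must be > 0")
  chk(cfg$series_resistance > 0, "series_resistance", "must be > 0")
  chk(cfg$dt > 0, "dt", "must be > 0")
  chk(cfg$duration >= cfg$stimulus_onset + cfg$stimulus_duration,
      "duration", "must cover the stimulus window")
  invisible(cfg)
}

#' Expand a flat run configuration into model parameter objects
#'
#' @param cfg `run_config`.
#' @return `network_config` built from the flat fields.
#' @export
as_network_config <- function(cfg) {
  network_config(
    n_cortical = cfg$n_cortical, fan_in = cfg$fan_in,
    neuron_params = neuron_params(
      capacitance = cfg$capacitance,
      leak_conductance = cfg$leak_conductance,
      leak_reversal = cfg$leak_reversal,
      na_max_conductance = cfg$na_max_conductance,
      na_reversal = cfg$na_reversal,
      k_max_conductance = cfg$k_max_conductance,
      k_reversal = cfg$k_reversal,
      threshold_shift = cfg$threshold_shift),
    cortical_synapse = synapse_params(
      peak_conductance = cfg$syn_peak_conductance,
      rise_time = cfg$syn_rise_time, decay_tau = cfg$syn_decay_tau,
      reversal = cfg$syn_reversal, depressing = TRUE,
      depression_factor = cfg$depression_factor,
      recovery_tau = cfg$recovery_tau),
    lgn_synapse = synapse_params(
      peak_conductance = cfg$syn_peak_conductance,
      rise_time = cfg$syn_rise_time, decay_tau = cfg$syn_decay_tau,
      reversal = cfg$syn_reversal, depressing = FALSE,
      depression_factor = cfg$depression_factor,
      recovery_tau = cfg$recovery_tau),
    lgn_targets = cfg$lgn_targets,
    lgn = lgn_params(cfg$lgn_rate, cfg$lgn_refractory),
    synaptic_delay = cfg$synaptic_delay,
    dt = cfg$dt,
    spike_threshold = cfg$spike_threshold,
    spike_refractory = cfg$spike_refractory)
}

#' Load a run configuration from a YAML document
#'
#' Missing fields take the reference defaults; unknown fields are
#' rejected with a message naming the offender.
#'
#' @param path Path to a YAML file (an empty document yields the full
#'   reference configuration).
#' @return `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rn_stop(sprintf("config file not found: %s", path), "invalid_config")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  do.call(run_config, doc)
}

#' Save a run configuration as YAML
#'
#' @param cfg `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable digest of a configuration
#'
#' Hash of the canonical JSON serialization of all fields; identical
#' digests imply identical model parameters, which together with the seed
#' fully determine every trace the package produces.
#'
#' @param cfg `run_config`, `network_config`, or any serializable list.
#' @return Character digest.
#' @export
config_digest <- function(cfg) {
  canon <- jsonlite::toJSON(strip_classes(cfg), digits = NA,
                            auto_unbox = TRUE)
  rlang::hash(as.character(canon))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else {
    x <- unclass(x)
    attributes(x) <- if (!is.null(names(x))) list(names = names(x)) else NULL
  }
  x
}

#' Write / read simulation traces as CSV plus a JSON sidecar
#'
#' The CSV holds the long trace table (`time_ms`, `neuron`, `v_mV`,
#' `i_vc_pA`, `i_lgn_pA`); the sidecar (same path with extension
#' `.json`) holds seed, step size, stimulus, replay mode, spike times and
#' the configuration digest.  The round trip is lossless: numbers are
#' serialized at full precision.
#'
#' @param result `sim_result`.
#' @param path CSV path (sidecar path derived from it).
#' @return `path` (write) or a `sim_result` (read).
#' @export
write_traces <- function(result, path) {
  labels <- colnames(result$V)
  tab <- data.frame(
    time_ms = rep(result$time, times = length(labels)),
    neuron = rep(labels, each = length(result$time)),
    v_mV = as.vector(result$V),
    i_vc_pA = as.vector(result$I_vc),
    i_lgn_pA = as.vector(result$I_lgn))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,neuron,v_mV,i_vc_pA,i_lgn_pA", con)
  writeLines(sprintf("%.17g,%s,%.17g,%.17g,%.17g", tab$time_ms, tab$neuron,
                     tab$v_mV, tab$i_vc_pA, tab$i_lgn_pA), con)
  sidecar <- list(
    seed = result$seed, dt = result$dt, duration = result$duration,
    stimulus = unclass(result$stimulus), mode = result$mode,
    clamp_enabled = result$clamp_enabled,
    config_digest = result$config_digest,
    neurons = labels,
    # spike times are integer multiples of dt; store the step indices so
    # the round trip is exact
    spike_steps = lapply(result$spikes, function(s) as.integer(round(s / result$dt))))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path) || !file.exists(sidecar_path(path))) {
    rn_stop(sprintf("trace file or sidecar missing for %s", path),
            "parse_error")
  }
  tab <- tryCatch(
    read.csv(path, colClasses = c(time_ms = "numeric", neuron = "character",
                                  v_mV = "numeric", i_vc_pA = "numeric",
                                  i_lgn_pA = "numeric")),
    error = function(e) rn_stop(sprintf("malformed trace CSV %s: %s", path,
                                        conditionMessage(e)), "parse_error"))
  side <- jsonlite::fromJSON(sidecar_path(path), simplifyVector = TRUE)
  labels <- side$neurons
  n_time <- length(unique(tab$time_ms))
  if (nrow(tab) != n_time * length(labels) ||
      !setequal(unique(tab$neuron), labels)) {
    rn_stop("trace CSV and sidecar disagree on neurons or grid length",
            "parse_error")
  }
  shape <- function(col) {
    m <- matrix(col, nrow = n_time, ncol = length(labels))
    colnames(m) <- labels
    m
  }
  spikes <- lapply(side$spike_steps, function(s) as.numeric(s) * side$dt)
  names(spikes) <- labels
  res <- list(time = tab$time_ms[seq_len(n_time)],
              V = shape(tab$v_mV), I_vc = shape(tab$i_vc_pA),
              I_lgn = shape(tab$i_lgn_pA),
              spikes = spikes,
              dt = side$dt, duration = side$duration, seed = side$seed,
              stimulus = structure(side$stimulus, class = "hue_stimulus"),
              mode = side$mode, clamp_enabled = side$clamp_enabled,
              config_digest = side$config_digest)
  class(res) <- "sim_result"
  res
}
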