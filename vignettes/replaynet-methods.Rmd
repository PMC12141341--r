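---
title: "Model and methods behind replaynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind replaynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

replaynet simulates a deliberately small "visual brain": five identical
cortical neurons wired in a ring, driven by two lateral geniculate nucleus
(LGN) input nodes, performing a toy *hue computation* — green light ignites
the whole network, red or blue drives exactly one neuron.  On top of the
network sit two *replay* mechanisms that re-impose a previously recorded
run on the same neurons, and a discrete Turing-machine analogue of the same
idea.  This vignette explains the model, the parameters that matter, the
numerical choices, and what the package's tests do and do not establish.

## Neuron model

Each cortical neuron is a single compartment with Hodgkin–Huxley Na⁺, K⁺
and leak currents:

$$C \frac{dV}{dt} = -g_L (V - E_L) - \bar g_{Na} m^3 h (V - E_{Na})
  - \bar g_K n^4 (V - E_K) + I_{syn} + I_{inj}$$

with `C = 200` pF, `g_L = 20` nS, `E_L = -70` mV, `E_Na = +50` mV,
`E_K = -77` mV.  The two hard constraints the model must satisfy are a
passive input resistance of 50 MΩ (`1/g_L`, verified by a hyperpolarizing
current-probe measurement, not assumed) and a membrane time constant of
10 ms (`C/g_L`).

The gating kinetics are Traub–Miles-style rate functions with a voltage
offset (`threshold_shift`).  The alternative — classic squid-axon rates
shifted along the voltage axis — was rejected because the squid
delayed-rectifier gate is substantially open at −70 mV, which both moves
the resting potential off `E_L` and adds a resting K⁺ conductance that
breaks the 50 MΩ target.  With the Traub-style rates all gates are
effectively closed at rest, so rest sits at `E_L` and the measured input
resistance equals `1/g_L` to better than 0.5%.

`threshold_shift = -64` mV places the effective spike threshold near
−60 mV.  This value is a *network* calibration, not a single-cell one: the
hue computation requires that one full-strength 5 nS synaptic potential
(peak ≈ 6.5 mV) stays subthreshold while the near-coincident drive of two
presynaptic sources crosses threshold.  The package's selectivity tests
(green → 5 firing neurons, red/blue → exactly 1, across seeds) enforce
this margin; the chosen value passes 120/120 randomized runs.  Maximal
conductances are `ḡ_Na = 6000` nS and `ḡ_K = 1200` nS, giving a rheobase
near 225 pA, i.e. a 300 pA step fires the cell robustly.

## Synapses

A presynaptic spike increments a difference-of-exponentials conductance

$$g(t) = A\,(e^{-t/\tau_d} - e^{-t/\tau_r}), \qquad \tau_d = 10\ \mathrm{ms},$$

normalized so that a single event at full strength peaks at exactly
`g_syn = 5` nS.  The *rise time* parameter (2 ms) is defined as the time
from the event to the conductance peak — the quantity one would read off
an experimental trace — and the internal rise constant is solved from it
(τ_r ≈ 0.700 ms for τ_d = 10 ms).  Parameterizing by time-to-peak rather
than by τ_r keeps both printed kinetic numbers directly measurable from a
simulated transient: an exponential fit to the tail returns τ_d, and the
argmax returns the rise time.

Cortical (recurrent) synapses depress: after each presynaptic spike the
strength `s ∈ (0, 1]` is multiplied by 0.5 and then recovers as
`ds/dt = (1 − s)/τ_rec` with `τ_rec = 1` s.  The event amplitude is
`s · g_syn`, using `s` *before* the drop.  Depression is what stops
recurrent activity from running away: once the stimulus ends, the
depressed ring cannot sustain itself, and the tests check that firing
ceases within 200 ms of stimulus offset.  LGN afferent synapses do not
depress.  All synapses are excitatory with a 0 mV reversal and a 1 ms
delay; the delay removes same-step causality ambiguity in discrete time.

## LGN input and hue encoding

Each LGN node, while active, emits a renewal spike train: a 2 ms dead time
followed by an exponential interval with mean 8 ms, so the mean rate
*including* the refractory period is 100 spikes/s.  The hue map is:
green activates both nodes, red only the node targeting neuron *b*, blue
only the node targeting neuron *a*, and "none" neither.

The train of a node is a pure function of `(run_seed, node_id)` — not of
the hue and not of the other node.  This seeding contract is what makes
"congruent stimulus" a well-defined notion during replay: presenting red
with the same run seed as a green recording feeds neuron *b* the
*identical* afferent train it received during the recording, so any clamp
current on *b* reflects a genuine intervention rather than stimulus
sampling noise.

Stimulus timing defaults to onset 100 ms, duration 300 ms, total run
500 ms — enough for a pre-stimulus baseline, a steady response, and the
post-stimulus decay, while keeping a full run at 20,001 samples per neuron
(dt = 0.025 ms) and well under a second of compute.

## Integration scheme

Gates advance by exponential Euler against the pre-step voltage; the
voltage update is semi-implicit (backward): all conductances multiply the
end-of-step voltage, so the update is a ratio with a strictly positive
denominator.  This matters for the feedback clamp, whose conductance
equivalent (`1/R_s = 50,000` nS at the default 0.02 MΩ) is three orders of
magnitude stiffer than the membrane: treated explicitly it would force
dt ≪ 4 µs, treated implicitly it is unconditionally stable at
dt = 0.025 ms.  Spike detection is an upward crossing of 0 mV with a 2 ms
refractory rule, applied online to drive synapses (so clamped and
overwritten neurons still drive their targets) and available offline as
`detect_spikes()`; the two agree exactly on simulated traces.
Step-size adequacy is tested by spike-count agreement with a 10× finer
integration over randomized current traces, and rest is verified to be a
fixed point to within 0.01 mV over 500 ms.

## Replay mechanisms

`record_reference_run()` stores every neuron's voltage trace bit-for-bit
together with seed, stimulus, and a configuration digest.  Replay comes in
two flavors:

* **Feedforward**: each neuron's voltage is overwritten sample-by-sample
  with the recording.  Ongoing synaptic input is ignored (connections are
  effectively severed), so the replayed voltages are exact by
  construction.
* **Feedback**: a voltage clamp per neuron injects
  `I_vc = (V_cmd − V_m)/R_s`, solved inside the implicit voltage update
  against the *end-of-step* command sample.  Current flows only where
  ongoing activity deviates from the command.

The series resistance default is 0.02 MΩ, a clamp time constant of
`R_s · C = 4` µs — 2,500× faster than the membrane and 0.16 integration
steps.  The choice is driven by a quantitative requirement: during replay
in the dark, the clamp current into an LGN-driven neuron must reproduce
the LGN current recorded in the reference run (normalized RMS error below
5%).  The clamp's finite gain contributes a tracking error proportional to
`R_s`; at 0.1 MΩ the error is ~9%, at 0.02 MΩ it is ~1.7%.  Because the
end-of-step command sample enters the implicit solve, a run whose free
dynamics already match the command reproduces the recorded trajectory to
floating-point accuracy and the clamp current stays at the 10⁻⁹ pA level —
this is what makes the congruent-replay null exact rather than merely
small, and it also means the clamp *suppresses* rather than amplifies
rounding perturbations (per-step contraction ≈ 0.1).

Three outcomes are distinguished by `classify_nothing()`: clamp hardware
off (`NOTHING_TYPE_I`), clamp on but silent within a 1 pA tolerance
(`NOTHING_TYPE_II`), and everything else (`INTERVENTION`).  The 1 pA
tolerance sits ~9 orders of magnitude above the floating-point noise floor
of the congruent case and two orders below the smallest synaptic currents
in this network, so the classification is insensitive to its exact value.

## The scenario battery

Eight scenarios fan out from one base seed (per-scenario seeds are derived
deterministically; replay scenarios reuse the green recording's seed, which
is the congruence contract): three open-loop recordings (green/red/blue
selectivity), feedforward and feedback replay in the dark (equivalence and
fidelity), feedback replay under an incongruent red stimulus (the clamp
recreates only the missing node-1 input: peak |I_vc| > 100 pA on neuron
*a*, ≤ 1 pA on neuron *b*), feedback replay under the congruent green
stimulus (no current anywhere), and a clamp-off green control.  The
battery's pass predicates *are* the qualitative claims of the underlying
experiment; `summarize_battery()` serializes them as one row per scenario.
A full battery is ~25 network runs of 500 ms and completes in under a
second.

## The Turing-machine analogue

The same record/replay logic is restated for a deterministic Turing
machine.  Recording stores one `(s, t, w, m)` tuple per step (state, read
symbol, written symbol, move).  Feedforward replay applies the recorded
`(w, m)` sequence blind to tape and transition function.  Feedback replay
lets the live machine propose each `(w, m)` and intervenes — applying the
recorded pair instead — only on deviation; on the recorded tape it
intervenes zero times, yet the realized write/move sequence equals the
record on *every* tape.  Two conventions required a decision:

* The monitor compares only the proposed `(w, m)`, not the state: reads
  are fixed by the tape and states follow the transition function, so for
  deterministic machines comparing states too is observationally
  identical.
* The reachable-state set "along the recorded path" includes the terminal
  state the last recorded transition lands in.  This makes free execution
  on exactly the recorded tape coincide with the replay set, while any
  ensemble whose free runs visit additional states shows a strictly larger
  free set — those extra states are the erased counterfactuals.

The fixture machines (a two-state unary incrementer and a four-state
parity checker whose even/odd branches halt in disjoint states) are small
enough that every property is checked against brute-force execution.

## What the synthetic data does and does not show

Everything in this package is synthetic by design: the LGN renewal trains
are the only stochastic element, and every run is bit-reproducible from
`(configuration digest, seed)`.  The generator emulates stationary,
uncorrelated afferent drive at a fixed rate; it does not emulate
rate adaptation, inter-node correlations, oscillations, or any retinal
processing beyond the hue→node map.  Passing the battery therefore shows
that the *mechanisms* — selectivity via coincidence plus depression,
clamp-based reconstruction of missing input, the congruent null — behave
as described in a noiseless, perfectly observed, five-neuron setting.  It
does not show robustness to biological variability, to partial-population
clamping, or to command voltages recorded under a different model
configuration (the configuration digest guards against the latter).

## Degenerate inputs and edge cases

Constructors validate their invariants (conductances > 0, depression
factor in (0, 1], rise < decay, injective LGN targets, fan-in smaller than
the network).  A zero or depolarizing probe current, a spike during the
input-resistance probe, a replay against a mismatched time grid, an empty
scenario battery, a transition function with a hole, and a zero reference
current in the reconstruction error all raise classed errors rather than
returning numbers.  Non-finite voltages abort the integration naming the
neuron and time.  Ties in spike detection are resolved by the refractory
rule (first crossing wins); conductance states are clipped at zero in the
pathological case where the rise component exceeds the decay component by
rounding.

## Problem sizes

Default runs are 500 ms at dt = 0.025 ms (20,000 steps, 5 neurons,
17 synapses); the full test suite executes a few hundred such runs plus
two 10-s single-neuron property runs and completes in well under a minute;
the battery plus calibration plus the Turing-machine suite stays within
single-digit seconds.  These sizes were chosen as the smallest that leave
comfortable pre/post-stimulus baselines and statistically stable spike
counts.
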