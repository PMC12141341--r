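# shared fixtures, memoized so expensive runs happen once per suite
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ref_config <- function() cached("ref_config", network_config())

# green reference recording used across replay tests (seed fixed)
green_recording <- function() {
  cached("green_recording",
         record_reference_run(ref_config(), hue_stimulus("green"), 500,
                              seed = 11))
}

fb_nostim <- function() {
  cached("fb_nostim",
         run_with_replay(ref_config(), hue_stimulus("none", 100, 0),
                         green_recording(), "feedback"))
}

ff_nostim <- function() {
  cached("ff_nostim",
         run_with_replay(ref_config(), hue_stimulus("none", 100, 0),
                         green_recording(), "feedforward"))
}

fb_congruent <- function() {
  cached("fb_congruent",
         run_with_replay(ref_config(), hue_stimulus("green"),
                         green_recording(), "feedback"))
}

fb_incongruent <- function() {
  cached("fb_incongruent",
         run_with_replay(ref_config(), hue_stimulus("red"),
                         green_recording(), "feedback"))
}

clamp_off_green <- function() {
  cached("clamp_off_green",
         run_with_replay(ref_config(), hue_stimulus("green"),
                         green_recording(), "off"))
}

ref_battery <- function() cached("ref_battery", run_battery(7))

# parity-checker fixtures: odd "green" tape vs even "red" tape
parity_fixture <- function() {
  cached("parity_fixture", {
    spec <- tm_parity_checker()
    green <- c("1", "0", "1", "1")
    red <- c("1", "0", "0", "1")
    list(spec = spec, green = green, red = red,
         rec = tm_run_and_record(spec, green))
  })
}
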