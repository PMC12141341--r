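#' Turing-machine specification
#'
#' A deterministic machine over a finite tape alphabet.  The transition
#' table must be total on non-halting states for every symbol that can be
#' read; the head moves one cell left or right each step.
#'
#' @param states Character vector of state names.
#' @param alphabet Character vector of tape symbols, including the blank.
#' @param blank The blank symbol (read from unvisited cells).
#' @param transitions `data.frame` with columns `state`, `read`,
#'   `next_state`, `write`, `move` (`"L"` or `"R"`).
#' @param initial Initial state.
#' @param halting Character vector of halting states.
#' @return An object of class `tm_spec`.
#' @export
tm_spec <- function(states, alphabet, blank, transitions, initial, halting) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  needed <- c("state", "read", "next_state", "write", "move")
  if (!all(needed %in% names(transitions))) {
    rn_stop("transitions must have columns state, read, next_state, write, move",
            "malformed_spec")
  }
  if (!all(transitions$move %in% c("L", "R"))) {
    rn_stop("moves must be L or R", "malformed_spec")
  }
  if (!blank %in% alphabet) rn_stop("blank must be in alphabet",
                                    "malformed_spec")
  if (!initial %in% states) rn_stop("initial state unknown", "malformed_spec")
  if (anyDuplicated(transitions[c("state", "read")])) {
    rn_stop("duplicate transition for a (state, read) pair", "malformed_spec")
  }
  spec <- list(states = states, alphabet = alphabet, blank = blank,
               transitions = transitions, initial = initial,
               halting = halting)
  class(spec) <- "tm_spec"
  spec
}

# tape: character vector of symbols; position i (1-based). Cells outside
# are blank. Head starts at cell 1.
tape_read <- function(tape, pos, blank) {
  if (pos >= 1 && pos <= length(tape) && !is.na(tape[pos])) tape[pos] else blank
}

tape_write <- function(tape, pos, sym, blank) {
  if (pos > length(tape)) tape[seq(length(tape) + 1, pos)] <- blank
  if (pos < 1) rn_stop("head moved left of the tape origin", "tape_underflow")
  tape[pos] <- sym
  tape
}

lookup_transition <- function(spec, state, sym) {
  tr <- spec$transitions
  row <- tr[tr$state == state & tr$read == sym, ]
  if (nrow(row) == 0) {
    rn_stop(sprintf("malformed spec: no transition for (%s, %s)", state, sym),
            "malformed_spec")
  }
  row[1, ]
}

#' Run a Turing machine and record every head operation
#'
#' Standard execution from the initial state with the head on cell 1; one
#' `(s, t, w, m)` tuple — current state, read symbol, written symbol, head
#' move — is appended to the head record per step.  Stops on reaching a
#' halting state or after `max_steps`.
#'
#' @param spec `tm_spec`.
#' @param tape Character vector of initial tape symbols (cell 1 first).
#' @param max_steps Step budget; must be positive.
#' @return List with `record` (a `head_record` data.frame of columns
#'   `step`, `s`, `t`, `w`, `m`), `final_tape`, `halted`, and
#'   `visited_states`.
#' @export
tm_run_and_record <- function(spec, tape, max_steps = 10000) {
  if (max_steps <= 0) rn_stop("max_steps must be > 0", "invalid_params")
  state <- spec$initial
  pos <- 1L
  steps <- list()
  visited <- state
  halted <- FALSE
  for (k in seq_len(max_steps)) {
    if (state %in% spec$halting) { halted <- TRUE; break }
    sym <- tape_read(tape, pos, spec$blank)
    tr <- lookup_transition(spec, state, sym)
    steps[[k]] <- data.frame(step = k, s = state, t = sym, w = tr$write,
                             m = tr$move, stringsAsFactors = FALSE)
    tape <- tape_write(tape, pos, tr$write, spec$blank)
    pos <- pos + if (tr$move == "R") 1L else -1L
    state <- tr$next_state
    visited <- union(visited, state)
  }
  if (!halted && state %in% spec$halting) halted <- TRUE
  record <- if (length(steps) == 0) {
    data.frame(step = integer(0), s = character(0), t = character(0),
               w = character(0), m = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, steps)
  class(record) <- c("head_record", class(record))
  list(record = record, final_tape = tape, halted = halted,
       visited_states = visited)
}

#' Feedforward replay of a head record
#'
#' Applies the recorded `(w, m)` sequence verbatim: the transition function
#' and the tape's read symbols are never consulted, so the same writes land
#' on the same cells whatever the tape contains.  The machine's own
#' dynamics are bypassed entirely, so "interventions" are not defined for
#' this mode (`NA`).
#'
#' @param record `head_record` from [tm_run_and_record()].
#' @param tape Initial tape (character vector).
#' @param blank Symbol used to pad cells the head skips over.
#' @return List of class `tm_replay_result`: `final_tape`, `halted`
#'   (`TRUE`: the replay ran to the end of the record), `interventions`
#'   (`NA`), `visited_states` (the recorded states), and `ops`
#'   (the realized `(w, m)` sequence).
#' @export
tm_feedforward_replay <- function(record, tape, blank = "_") {
  if (nrow(record) == 0) rn_stop("record is empty", "invalid_params")
  pos <- 1L
  for (k in seq_len(nrow(record))) {
    tape <- tape_write(tape, pos, record$w[k], blank = blank)
    pos <- pos + if (record$m[k] == "R") 1L else -1L
  }
  res <- list(final_tape = tape, halted = TRUE,
              interventions = NA_integer_,
              visited_states = unique(record$s),
              ops = record[, c("w", "m")])
  class(res) <- "tm_replay_result"
  res
}

#' Feedback replay of a head record
#'
#' Each step the live machine proposes `(w, m)` by running its transition
#' function on the current configuration.  If the proposal matches the
#' recorded tuple it is applied untouched (the replay only monitors); if
#' it deviates — or the machine has halted or lacks a transition — the
#' recorded `(w, m)` is applied instead and the intervention counter is
#' incremented.  The realized write/move sequence therefore always equals
#' the record, and on the recorded tape itself no interventions occur.
#'
#' The monitor compares only the proposed `(w, m)` pair: reads are fixed by
#' the tape and states follow the transition function, so for a
#' deterministic machine comparing states as well would be observationally
#' identical.
#'
#' @param spec `tm_spec`.
#' @param record `head_record`.
#' @param tape Initial tape.
#' @return `tm_replay_result` with the intervention count and the recorded
#'   states as `visited_states`.
#' @export
tm_feedback_replay <- function(spec, record, tape) {
  if (nrow(record) == 0) rn_stop("record is empty", "invalid_params")
  state <- spec$initial
  pos <- 1L
  interventions <- 0L
  for (k in seq_len(nrow(record))) {
    proposed <- NULL
    if (!state %in% spec$halting) {
      sym <- tape_read(tape, pos, spec$blank)
      tr <- lookup_transition(spec, state, sym)
      proposed <- c(tr$write, tr$move)
      next_state <- tr$next_state
    }
    if (is.null(proposed) ||
        proposed[1] != record$w[k] || proposed[2] != record$m[k]) {
      interventions <- interventions + 1L
      if (is.null(proposed)) next_state <- state
    }
    tape <- tape_write(tape, pos, record$w[k], spec$blank)
    pos <- pos + if (record$m[k] == "R") 1L else -1L
    state <- next_state
  }
  res <- list(final_tape = tape, halted = TRUE,
              interventions = interventions,
              visited_states = unique(record$s),
              ops = record[, c("w", "m")])
  class(res) <- "tm_replay_result"
  res
}

#' Reachable states of a machine over a tape ensemble
#'
#' In free mode every tape is executed brute force and the visited states
#' are pooled.  Under feedback replay the machine can only traverse the
#' recorded path, whatever the tape: the reachable set collapses to the
#' states along the record — the per-step states plus the terminal state
#' the last recorded transition lands in.  States reachable in free mode
#' but absent from the record are exactly the counterfactuals the replay
#' erases; when the ensemble is just the recorded tape, free execution
#' retraces the record and the two sets coincide.
#'
#' @param spec `tm_spec`.
#' @param tapes List of initial tapes (character vectors).
#' @param mode `"free"` or `"feedback_replay"`.
#' @param record `head_record`; required in replay mode.
#' @param max_steps Step budget per free run.
#' @return Character vector of reachable state names.
#' @export
reachable_state_set <- function(spec, tapes, mode = c("free",
                                                      "feedback_replay"),
                                record = NULL, max_steps = 10000) {
  mode <- match.arg(mode)
  if (mode == "feedback_replay") {
    if (is.null(record)) rn_stop("replay mode requires a record",
                                 "invalid_params")
    return(record_path_states(spec, record))
  }
  Reduce(union, lapply(tapes, function(tp) {
    tm_run_and_record(spec, tp, max_steps)$visited_states
  }), accumulate = FALSE)
}

# states the recorded trajectory passes through: the per-step states and
# the terminal state of the last recorded transition
record_path_states <- function(spec, record) {
  if (nrow(record) == 0) return(character(0))
  last <- lookup_transition(spec, record$s[nrow(record)],
                            record$t[nrow(record)])
  union(unique(record$s), last$next_state)
}

#' Fixture machine: unary incrementer
#'
#' Scans right over a block of 1s and appends one more 1 at the first
#' blank, then halts.  Two working states over the alphabet `{1, _}`.
#'
#' @return `tm_spec`.
#' @export
tm_unary_incrementer <- function() {
  tm_spec(
    states = c("scan", "done"),
    alphabet = c("1", "_"),
    blank = "_",
    transitions = data.frame(
      state = c("scan", "scan"),
      read = c("1", "_"),
      next_state = c("scan", "done"),
      write = c("1", "1"),
      move = c("R", "R"),
      stringsAsFactors = FALSE),
    initial = "scan",
    halting = "done")
}

#' Fixture machine: bit-string parity checker
#'
#' Tracks the parity of 1s while scanning right over `{0, 1}` and, at the
#' first blank, stamps `E` or `O` and halts in a parity-specific state
#' (four states in total), so even and odd inputs reach disjoint
#' terminal states.
#'
#' @return `tm_spec`.
#' @export
tm_parity_checker <- function() {
  tm_spec(
    states = c("even", "odd", "accept_even", "accept_odd"),
    alphabet = c("0", "1", "E", "O", "_"),
    blank = "_",
    transitions = data.frame(
      state = c("even", "even", "even", "odd", "odd", "odd"),
      read = c("0", "1", "_", "0", "1", "_"),
      next_state = c("even", "odd", "accept_even", "odd", "even",
                     "accept_odd"),
      write = c("0", "1", "E", "0", "1", "O"),
      move = c("R", "R", "R", "R", "R", "R"),
      stringsAsFactors = FALSE),
    initial = "even",
    halting = c("accept_even", "accept_odd"))
}

#' Read / write a Turing-machine spec as JSON
#'
#' @param path File path.
#' @return `tm_spec` (read) or `path` invisibly (write).
#' @export
read_tm_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tm_spec(states = doc$states, alphabet = doc$alphabet, blank = doc$blank,
          transitions = doc$transitions, initial = doc$initial,
          halting = doc$halting)
}

#' @rdname read_tm_spec
#' @param spec `tm_spec` to serialize.
#' @export
write_tm_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a head record as CSV
#'
#' Columns `step, s, t, w, m`, one row per executed step.
#'
#' @param path File path.
#' @return `head_record` (read) or `path` invisibly (write).
#' @export
read_head_record <- function(path) {
  rec <- read.csv(path, colClasses = c(step = "integer", s = "character",
                                       t = "character", w = "character",
                                       m = "character"))
  class(rec) <- c("head_record", class(rec))
  rec
}

#' @rdname read_head_record
#' @param record `head_record` to serialize.
#' @export
write_head_record <- function(record, path) {
  write.csv(as.data.frame(unclass(record))[, c("step", "s", "t", "w", "m")],
            path, row.names = FALSE)
  invisible(path)
}
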