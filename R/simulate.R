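#' Specify a Markov chain for event-log simulation
#'
#' A chain is given by its state labels, an initial-state probability vector,
#' and a transition matrix in which each row either is row-stochastic (sums
#' to one) or is marked terminal -- an absorbing stop: a trace ends as soon
#' as it enters a terminal state. Modelling termination with terminal rows
#' (rather than an artificial END label) keeps generated logs free of
#' synthetic activities. \code{max_trace_length} guards against
#' non-terminating chains; truncated traces are flagged and counted.
#'
#' @param states ordered character vector of distinct state labels.
#' @param initial probability vector over \code{states}; must sum to 1
#'   (tolerance 1e-9).
#' @param transitions square numeric matrix, \code{length(states)} on a side,
#'   rows/columns in the order of \code{states}. Non-terminal rows must sum
#'   to 1 (tolerance 1e-9) with non-negative entries.
#' @param terminal character vector of terminal state labels. Defaults to the
#'   states whose transition row is all zero.
#' @param max_trace_length positive integer cap on simulated trace length.
#' @return An object of class \code{"markov_chain_spec"}.
#' @examples
#' spec <- markov_chain_spec(
#'   states = c("a", "b"),
#'   initial = c(1, 0),
#'   transitions = rbind(c(0, 1), c(0, 0)),
#'   terminal = "b")
#' sample_trace(spec)
#' @export
markov_chain_spec <- function(states, initial, transitions, terminal = NULL,
                              max_trace_length = 50L) {
  states <- as.character(states)
  k <- length(states)
  if (k == 0 || anyDuplicated(states) || any(!nzchar(states))) {
    stop("states must be a non-empty vector of distinct non-empty labels",
         call. = FALSE)
  }
  if (length(initial) != k || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a length-", k,
         " probability vector summing to 1", call. = FALSE)
  }
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(k, k))) {
    stop("transitions must be a ", k, " x ", k, " matrix", call. = FALSE)
  }
  if (any(transitions < 0)) {
    stop("transition probabilities must be non-negative", call. = FALSE)
  }
  dimnames(transitions) <- list(states, states)
  row_sums <- rowSums(transitions)
  if (is.null(terminal)) {
    terminal <- states[row_sums == 0]
  } else {
    terminal <- as.character(terminal)
    if (!all(terminal %in% states)) {
      stop("terminal states must be among the chain's states", call. = FALSE)
    }
  }
  is_term <- states %in% terminal
  bad <- which(!is_term & abs(row_sums - 1) > 1e-9)
  if (length(bad) > 0) {
    stop("non-terminal transition row(s) must sum to 1: ",
         paste(states[bad], collapse = ", "), call. = FALSE)
  }
  max_trace_length <- as.integer(max_trace_length)
  if (is.na(max_trace_length) || max_trace_length < 1) {
    stop("max_trace_length must be a positive integer", call. = FALSE)
  }
  structure(list(states = states,
                 initial = stats::setNames(as.numeric(initial), states),
                 transitions = transitions,
                 terminal = states[is_term],
                 max_trace_length = max_trace_length),
            class = "markov_chain_spec")
}

#' @export
print.markov_chain_spec <- function(x, ...) {
  cat("Markov chain over ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  cat("terminal:", if (length(x$terminal)) paste(x$terminal, collapse = ", ")
      else "(none)", "\n")
  cat("transition matrix:\n")
  print(x$transitions)
  invisible(x)
}

#' Sample one trace from a Markov chain
#'
#' Draws the first state from the chain's initial distribution and successors
#' from the current state's transition row, stopping on entry to a terminal
#' state or at \code{max_trace_length} (in which case the returned trace
#' carries attribute \code{truncated = TRUE}). Uses and advances R's global
#' RNG; seed outside for reproducibility.
#'
#' @param spec a [markov_chain_spec()].
#' @return Character vector of state labels, length \eqn{\ge 1}.
#' @export
sample_trace <- function(spec) {
  stopifnot(inherits(spec, "markov_chain_spec"))
  cur <- sample(spec$states, 1, prob = spec$initial)
  out <- character(spec$max_trace_length)
  out[1] <- cur
  n <- 1L
  truncated <- FALSE
  while (!(cur %in% spec$terminal)) {
    if (n >= spec$max_trace_length) {
      truncated <- TRUE
      break
    }
    cur <- sample(spec$states, 1, prob = spec$transitions[cur, ])
    n <- n + 1L
    out[n] <- cur
  }
  structure(out[seq_len(n)], truncated = truncated)
}

#' Generate a synthetic two-cohort event log
#'
#' Samples \code{n_a} cases from \code{spec_a} and \code{n_b} from
#' \code{spec_b}, tagging them with \code{attribute_name} = \code{"True"} /
#' \code{"False"} respectively, so that [split_by_attribute()] recovers the
#' cohorts exactly. Order indices run 1..length within each case.
#'
#' One root seed drives an arithmetically derived per-case stream, so the
#' first \code{n_a} cases are unchanged when \code{n_b} varies, and a fixed
#' seed yields a byte-identical log after [write_event_log()].
#'
#' @param spec_a,spec_b [markov_chain_spec()] objects for the matching
#'   (\code{"True"}) and remainder (\code{"False"}) cohort.
#' @param n_a,n_b non-negative case counts per cohort.
#' @param attribute_name name of the cohort attribute column.
#' @param seed integer root seed.
#' @return An [event_log()]; attribute \code{n_truncated} counts traces cut
#'   at \code{max_trace_length} (also warned about when non-zero).
#' @examples
#' preset <- running_example_preset()
#' log <- generate_cohort_log(preset$emergency, preset$non_emergency,
#'                            n_a = 5, n_b = 5, seed = 1)
#' log
#' @export
generate_cohort_log <- function(spec_a, spec_b, n_a, n_b,
                                attribute_name = "Is Emergency", seed) {
  stopifnot(inherits(spec_a, "markov_chain_spec"),
            inherits(spec_b, "markov_chain_spec"),
            n_a >= 0, n_b >= 0)
  n_total <- n_a + n_b
  id_width <- max(1L, nchar(as.character(max(1, n_total))))
  traces <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    spec <- if (i <= n_a) spec_a else spec_b
    traces[[i]] <- with_seed(derive_case_seed(seed, i), sample_trace(spec))
  }
  n_truncated <- sum(vapply(traces, function(tr) isTRUE(attr(tr, "truncated")),
                            logical(1)))
  lens <- lengths(traces)
  case_id <- rep(sprintf(paste0("c%0", id_width, "d"), seq_len(n_total)), lens)
  cohort <- rep(ifelse(seq_len(n_total) <= n_a, "True", "False"), lens)
  log <- event_log(
    case_id = case_id,
    state = unlist(traces, use.names = FALSE),
    order = unlist(lapply(lens, seq_len), use.names = FALSE),
    attributes = stats::setNames(data.frame(cohort, stringsAsFactors = FALSE),
                                 attribute_name))
  if (n_truncated > 0) {
    warning(n_truncated, " trace(s) truncated at max_trace_length",
            call. = FALSE)
  }
  attr(log, "n_truncated") <- n_truncated
  log
}

#' Markov-chain presets for the hospital running example
#'
#' Two chains over the five activities register patient (rp), read patient's
#' journal (rj), visit patient (vp), update the journal (uj) and operate
#' patient (op). Both cohorts start by registering the patient. The
#' emergency chain sometimes operates directly after registration and never
#' visits; the non-emergency chain visits the patient, updates the journal
#' and occasionally loops back to re-read it before operating. The exact
#' probabilities are this package's own illustrative choice: they follow the
#' narrative, not any published sample data.
#'
#' @return List with elements \code{emergency} and \code{non_emergency},
#'   both [markov_chain_spec()] objects.
#' @examples
#' preset <- running_example_preset()
#' preset$emergency$transitions
#' @export
running_example_preset <- function() {
  st <- c("rp", "rj", "vp", "uj", "op")
  emergency <- markov_chain_spec(
    states = st,
    initial = c(1, 0, 0, 0, 0),
    transitions = rbind(
      rp = c(0, 0.70, 0, 0,    0.30),
      rj = c(0, 0,    0, 0.25, 0.75),
      vp = c(0, 0,    0, 0,    0),
      uj = c(0, 0,    0, 0,    1),
      op = c(0, 0,    0, 0,    0)),
    terminal = c("vp", "op"))
  non_emergency <- markov_chain_spec(
    states = st,
    initial = c(1, 0, 0, 0, 0),
    transitions = rbind(
      rp = c(0, 1,   0,   0,    0),
      rj = c(0, 0,   0.8, 0,    0.2),
      vp = c(0, 0,   0,   0.9,  0.1),
      uj = c(0, 0.4, 0,   0,    0.6),
      op = c(0, 0,   0,   0,    0)),
    terminal = "op")
  list(emergency = emergency, non_emergency = non_emergency)
}

#' Read a Markov-chain spec from a plain-text YAML config
#'
#' The config lists the states, the initial vector, optionally
#' \code{max_trace_length}, and one entry per state under \code{transitions}:
#' either a mapping \code{target: probability} or the word \code{terminal}.
#'
#' @param path path to a YAML file.
#' @return A [markov_chain_spec()].
#' @export
read_markov_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  states <- as.character(cfg$states)
  k <- length(states)
  trans <- matrix(0, k, k, dimnames = list(states, states))
  terminal <- character(0)
  for (s in states) {
    row <- cfg$transitions[[s]]
    if (is.null(row) || identical(row, "terminal")) {
      terminal <- c(terminal, s)
    } else {
      trans[s, names(row)] <- unlist(row)
    }
  }
  markov_chain_spec(states = states, initial = as.numeric(cfg$initial),
                    transitions = trans, terminal = terminal,
                    max_trace_length = cfg$max_trace_length %||% 50L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
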