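#' Fit a directly-follows graph to an event log
#'
#' Counts, across all cases, how often each ordered state pair (a, b) occurs
#' at consecutive positions of the same trace. Pairs never span two cases.
#' The result is the directly-follows graph (DFG): the de-facto process-map
#' representation, and the sufficient statistic for the first-order Markov
#' transition estimate produced by [to_stochastic()].
#'
#' Besides the edge frequencies the fitted object records, per state, how
#' often a trace starts or ends there; these counts power the
#' [simulate.stochastic_dfg()] method and the optional virtual start/end
#' nodes in rendering. Self-loops (a, a) are counted like any other pair.
#' An empty log, or a log of single-event traces, yields an empty graph.
#'
#' @param log an [event_log()].
#' @return An object of class \code{"dfg"}: a list with \code{edges} (data
#'   frame \code{source}, \code{target}, \code{freq}, sorted lexicographically
#'   by pair, only frequencies \eqn{\ge 1} stored), \code{states}, and the
#'   per-state \code{initial} / \code{terminal} counts.
#' @examples
#' path <- system.file("extdata", "hospital_log.csv", package = "dfgdiff")
#' log <- read_event_log(path)
#' d <- dfg(log)
#' d
#' total_pair_count(d)
#' @export
dfg <- function(log) {
  stopifnot(inherits(log, "event_log"))
  tr <- traces(log)
  src <- unlist(lapply(tr, function(s) s[-length(s)]), use.names = FALSE)
  tgt <- unlist(lapply(tr, function(s) s[-1]), use.names = FALSE)
  if (length(src) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        freq = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(freq = rep(1L, length(src))),
                            by = list(source = src, target = tgt), FUN = sum)
    edges <- agg[order(agg$source, agg$target), , drop = FALSE]
    rownames(edges) <- NULL
    edges$freq <- as.integer(edges$freq)
  }
  firsts <- vapply(tr, function(s) s[1], character(1))
  lasts <- vapply(tr, function(s) s[length(s)], character(1))
  new_dfg(edges,
          initial = count_table(firsts),
          terminal = count_table(lasts),
          n_cases = length(tr))
}

count_table <- function(x) {
  if (length(x) == 0) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

new_dfg <- function(edges, initial = NULL, terminal = NULL, n_cases = NULL) {
  structure(list(edges = edges,
                 states = sort(unique(c(edges$source, edges$target))),
                 initial = initial, terminal = terminal, n_cases = n_cases),
            class = "dfg")
}

#' Build a directly-follows graph from an explicit edge list
#'
#' Frequencies counted from a log are integers, but real-valued weights are
#' accepted here (and normalised by [to_stochastic()]) for forward
#' compatibility with weighted graphs.
#'
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{freq}; all frequencies must be \eqn{> 0} and pairs distinct.
#' @return A \code{"dfg"} object (without start/end counts, so it cannot be
#'   simulated from).
#' @export
as_dfg <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "freq") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(edges$freq <= 0) || anyNA(edges$freq)) {
    stop("all stored frequencies must be positive", call. = FALSE)
  }
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\x1f"))) {
    stop("duplicate (source, target) pair in edge list", call. = FALSE)
  }
  edges <- edges[order(edges$source, edges$target),
                 c("source", "target", "freq"), drop = FALSE]
  rownames(edges) <- NULL
  new_dfg(edges)
}

#' Total number of directly-follows pairs
#'
#' The sum of all stored edge frequencies. For a graph fitted from a log this
#' equals the sum over cases of (trace length - 1).
#'
#' @param x a \code{"dfg"}.
#' @return Non-negative number.
#' @export
total_pair_count <- function(x) {
  stopifnot(inherits(x, "dfg"))
  sum(x$edges$freq)
}

#' Normalise a directly-follows graph into transition probabilities
#'
#' Divides each edge frequency by the total outgoing frequency of its source
#' state, yielding the maximum-likelihood estimate of a first-order Markov
#' chain's transition probabilities. Sources with no outgoing edge (terminal
#' states) contribute no entries, so division by zero cannot arise; every
#' stored probability lies in (0, 1] and each source's outgoing probabilities
#' sum to one.
#'
#' @param x a [dfg()].
#' @return An object of class \code{"stochastic_dfg"} with \code{edges}
#'   (\code{source}, \code{target}, \code{prob}) plus the fitted graph's
#'   start/end counts and outgoing totals when available.
#' @examples
#' d <- as_dfg(data.frame(source = c("a", "a", "b"),
#'                        target = c("b", "c", "c"),
#'                        freq = c(2, 2, 1)))
#' to_stochastic(d)$edges
#' @export
to_stochastic <- function(x) {
  stopifnot(inherits(x, "dfg"))
  edges <- x$edges
  if (nrow(edges) == 0) {
    prob_edges <- data.frame(source = character(0), target = character(0),
                             prob = numeric(0), stringsAsFactors = FALSE)
    totals <- numeric(0)
  } else {
    totals <- tapply(edges$freq, edges$source, sum)
    prob_edges <- data.frame(source = edges$source, target = edges$target,
                             prob = edges$freq / as.numeric(totals[edges$source]),
                             stringsAsFactors = FALSE)
  }
  structure(list(edges = prob_edges, states = x$states,
                 out_totals = totals, initial = x$initial,
                 terminal = x$terminal, n_cases = x$n_cases),
            class = "stochastic_dfg")
}

#' Compare two stochastic directly-follows graphs
#'
#' For every ordered state pair stored in either graph, computes the signed
#' probability difference \eqn{d = p_a - p_b}, where a pair missing from one
#' graph contributes probability 0 (the only convention that keeps the
#' comparison antisymmetric and bounded in \eqn{[-1, 1]}). A pair is retained
#' iff \eqn{|d|} is strictly greater than the cut-off; ties at the cut-off
#' are excluded. The orientation (which cohort is the minuend) is recorded in
#' the result, since the sign carries the meaning.
#'
#' No significance test is applied: the cut-off is a deterministic threshold
#' on the probability scale, in the spirit of edge-filtering process
#' discovery algorithms.
#'
#' @param a,b \code{"stochastic_dfg"} objects (cohort a is the minuend).
#' @param cutoff threshold in \eqn{[0, 1)}; accepts a fraction (\code{0.2})
#'   or a percentage string (\code{"20\%"}).
#' @param labels length-2 character vector naming the minuend and subtrahend
#'   cohorts for display and serialization.
#' @return An object of class \code{"diff_dfg"} with \code{edges}
#'   (\code{source}, \code{target}, \code{diff}), the \code{cutoff} used, and
#'   the orientation labels.
#' @examples
#' a <- to_stochastic(as_dfg(data.frame(source = "x", target = "y", freq = 7)))
#' b <- to_stochastic(as_dfg(data.frame(source = c("x", "x"),
#'                                      target = c("y", "z"),
#'                                      freq = c(2, 3))))
#' compare_dfg(a, b, cutoff = 0.2)$edges
#' @export
compare_dfg <- function(a, b, cutoff = 0, labels = c("a", "b")) {
  stopifnot(inherits(a, "stochastic_dfg"), inherits(b, "stochastic_dfg"))
  cutoff <- parse_cutoff(cutoff)
  m <- merge(a$edges, b$edges, by = c("source", "target"), all = TRUE,
             suffixes = c("_a", "_b"))
  pa <- ifelse(is.na(m$prob_a), 0, m$prob_a)
  pb <- ifelse(is.na(m$prob_b), 0, m$prob_b)
  d <- pa - pb
  keep <- abs(d) > cutoff
  edges <- data.frame(source = m$source[keep], target = m$target[keep],
                      diff = d[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 states = sort(unique(c(a$states, b$states))),
                 cutoff = cutoff,
                 minuend = labels[[1]], subtrahend = labels[[2]]),
            class = "diff_dfg")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.dfg <- function(x, ...) {
  cat("Directly-follows graph: ", nrow(x$edges), " edges over ",
      length(x$states), " states (", total_pair_count(x),
      " directly-follows pairs)\n", sep = "")
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' @export
print.stochastic_dfg <- function(x, ...) {
  cat("Stochastic DFG (first-order Markov estimate): ", nrow(x$edges),
      " transitions over ", length(x$states), " states\n", sep = "")
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' @export
print.diff_dfg <- function(x, ...) {
  cat("DFG difference (", x$minuend, " minus ", x$subtrahend,
      "), cutoff ", format(x$cutoff), ": ", nrow(x$edges),
      " flows retained\n", sep = "")
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' Frequency / probability matrix of a directly-follows graph
#'
#' @param x a \code{"dfg"} or \code{"stochastic_dfg"}.
#' @param ... unused.
#' @return Square matrix indexed by state, zeros where no pair is stored.
#' @export
as.matrix.dfg <- function(x, ...) {
  edge_matrix(x$edges, x$states, "freq")
}

#' @rdname as.matrix.dfg
#' @export
as.matrix.stochastic_dfg <- function(x, ...) {
  edge_matrix(x$edges, x$states, "prob")
}

#' @rdname as.matrix.dfg
#' @export
as.matrix.diff_dfg <- function(x, ...) {
  edge_matrix(x$edges, x$states, "diff")
}

edge_matrix <- function(edges, states, value_col) {
  m <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  if (nrow(edges) > 0) {
    m[cbind(edges$source, edges$target)] <- edges[[value_col]]
  }
  m
}

#' Estimated transition matrix
#'
#' Rows are source states, columns target states. Rows of terminal states
#' (no observed outgoing transition) are all zero; every other row sums to
#' one.
#'
#' @param object a \code{"stochastic_dfg"}.
#' @param ... unused.
#' @return Row-(sub)stochastic matrix over the graph's states.
#' @export
coef.stochastic_dfg <- function(object, ...) {
  as.matrix(object)
}

#' Next-state distribution from a given state
#'
#' @param object a \code{"stochastic_dfg"}.
#' @param from a state label.
#' @param ... unused.
#' @return Named probability vector over the graph's states (all zero when
#'   \code{from} is terminal).
#' @export
predict.stochastic_dfg <- function(object, from, ...) {
  if (!from %in% object$states) {
    stop("unknown state ", sQuote(from), call. = FALSE)
  }
  coef(object)[from, ]
}

#' Simulate traces from a fitted stochastic DFG
#'
#' Generates traces from the estimated chain: the start state is drawn from
#' the empirical initial-state distribution, transitions follow the estimated
#' probabilities, and at each visit to a state the trace stops with the
#' empirically estimated stopping hazard (terminal visits over all visits of
#' that state). Only available for graphs fitted from a log via [dfg()],
#' which record the start/end counts.
#'
#' @param object a \code{"stochastic_dfg"} fitted from an event log.
#' @param nsim number of traces.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param max_length hard cap on trace length.
#' @param ... unused.
#' @return List of character vectors (traces).
#' @export
simulate.stochastic_dfg <- function(object, nsim = 1, seed = NULL,
                                    max_length = 50L, ...) {
  if (is.null(object$initial) || is.null(object$n_cases)) {
    stop("this stochastic DFG was not fitted from a log; ",
         "no initial-state information to simulate from", call. = FALSE)
  }
  all_states <- sort(unique(c(object$states, names(object$initial),
                              names(object$terminal))))
  term <- stats::setNames(rep(0, length(all_states)), all_states)
  term[names(object$terminal)] <- object$terminal
  outs <- stats::setNames(rep(0, length(all_states)), all_states)
  outs[names(object$out_totals)] <- object$out_totals
  stop_p <- ifelse(term + outs > 0, term / (term + outs), 1)
  trans <- edge_matrix(object$edges, all_states, "prob")
  init_p <- stats::setNames(rep(0, length(all_states)), all_states)
  init_p[names(object$initial)] <- object$initial / object$n_cases
  run <- function() {
    lapply(seq_len(nsim), function(i) {
      cur <- sample(all_states, 1, prob = init_p)
      out <- cur
      while (length(out) < max_length) {
        if (stats::runif(1) < stop_p[[cur]]) break
        cur <- sample(all_states, 1, prob = trans[cur, ])
        out <- c(out, cur)
      }
      out
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
summary.dfg <- function(object, ...) {
  cat("Directly-follows frequency matrix:\n")
  print(as.matrix(object))
  invisible(as.matrix(object))
}

#' @export
summary.stochastic_dfg <- function(object, ...) {
  cat("Estimated transition matrix (rows sum to 1; terminal rows zero):\n")
  m <- coef(object)
  print(round(m, 4))
  invisible(m)
}

#' Plot a process map
#'
#' Draws the graph with \pkg{igraph} (edge width scaled by frequency /
#' probability; for difference maps, negative flows dashed). For publication
#' maps use [dfg_to_dot()] / [diff_to_dot()] and an external Graphviz
#' renderer.
#'
#' @param x a \code{"dfg"}, \code{"stochastic_dfg"} or \code{"diff_dfg"}.
#' @param ... passed to \code{igraph::plot.igraph}.
#' @return The igraph object, invisibly.
#' @export
plot.dfg <- function(x, ...) {
  plot_edges(x$edges, x$states, x$edges$freq, lty = 1, ...)
}

#' @rdname plot.dfg
#' @export
plot.stochastic_dfg <- function(x, ...) {
  plot_edges(x$edges, x$states, x$edges$prob, lty = 1, ...)
}

#' @rdname plot.dfg
#' @export
plot.diff_dfg <- function(x, ...) {
  plot_edges(x$edges, x$states, abs(x$edges$diff),
             lty = ifelse(x$edges$diff < 0, 2, 1),
             label = sprintf("%.2f", x$edges$diff), ...)
}

plot_edges <- function(edges, states, weight, lty, label = NULL, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("package 'igraph' is required for plotting", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     vertices = states)
  w <- if (length(weight) > 0 && max(weight) > 0) 1 + 4 * weight / max(weight) else 1
  igraph::plot.igraph(g, edge.width = w, edge.lty = lty,
                      edge.label = if (is.null(label)) signif(weight, 3) else label,
                      ...)
  invisible(g)
}

# ---- edge-list serialization ----------------------------------------------

#' Write a graph as an edge-list CSV
#'
#' The file starts with a one-line metadata comment recording the graph kind
#' (\code{frequency}, \code{probability} or \code{difference}) and, for
#' difference graphs, the cut-off and orientation; then a CSV with columns
#' \code{source,target,value}, sorted by pair so output is byte-stable.
#'
#' @param x a \code{"dfg"}, \code{"stochastic_dfg"} or \code{"diff_dfg"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "diff_dfg")) {
    meta <- sprintf("# dfgdiff kind=difference cutoff=%s minuend=%s subtrahend=%s",
                    format(x$cutoff), quote_dot(x$minuend),
                    quote_dot(x$subtrahend))
    df <- data.frame(source = x$edges$source, target = x$edges$target,
                     value = x$edges$diff)
  } else if (inherits(x, "stochastic_dfg")) {
    meta <- "# dfgdiff kind=probability"
    df <- data.frame(source = x$edges$source, target = x$edges$target,
                     value = x$edges$prob)
  } else if (inherits(x, "dfg")) {
    meta <- "# dfgdiff kind=frequency"
    df <- data.frame(source = x$edges$source, target = x$edges$target,
                     value = x$edges$freq)
  } else {
    stop("not a dfg-like object", call. = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Read an edge-list CSV written by [write_edge_list()]
#'
#' @param path path to the edge-list file.
#' @return The reconstructed \code{"dfg"}, \code{"stochastic_dfg"} or
#'   \code{"diff_dfg"}.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- readLines(path, n = 1)
  kind <- sub('.*kind=([a-z]+).*', '\\1', meta)
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  if (kind == "frequency") {
    as_dfg(data.frame(source = df$source, target = df$target, freq = df$value))
  } else if (kind == "probability") {
    edges <- data.frame(source = as.character(df$source),
                        target = as.character(df$target), prob = df$value,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(edges = edges,
                   states = sort(unique(c(edges$source, edges$target))),
                   out_totals = NULL, initial = NULL, terminal = NULL,
                   n_cases = NULL),
              class = "stochastic_dfg")
  } else if (kind == "difference") {
    cutoff <- as.numeric(sub('.*cutoff=([0-9.eE+-]+).*', '\\1', meta))
    minuend <- sub('.*minuend="((?:[^"\\\\]|\\\\.)*)".*', '\\1', meta)
    subtrahend <- sub('.*subtrahend="((?:[^"\\\\]|\\\\.)*)".*', '\\1', meta)
    edges <- data.frame(source = as.character(df$source),
                        target = as.character(df$target), diff = df$value,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(edges = edges,
                   states = sort(unique(c(edges$source, edges$target))),
                   cutoff = cutoff,
                   minuend = gsub('\\\\"', '"', minuend),
                   subtrahend = gsub('\\\\"', '"', subtrahend)),
              class = "diff_dfg")
  } else {
    stop("unrecognised edge-list kind in ", path, call. = FALSE)
  }
}
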