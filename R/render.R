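#' Rendering options for process maps
#'
#' Controls label formatting and flow thickness when emitting Graphviz DOT.
#' Pen width is scaled affinely from \code{min_penwidth} to
#' \code{max_penwidth} over the range of edge values (absolute values for
#' difference maps); when all edges share one value the range is degenerate
#' and every edge gets \code{max_penwidth}.
#'
#' @param label_kind what the edge values are: \code{"frequency"} (integers),
#'   \code{"probability"} or \code{"difference"} (fixed-point with
#'   \code{decimals} digits). Normally inferred from the object being
#'   rendered.
#' @param decimals digits after the decimal point for probability and
#'   difference labels.
#' @param min_penwidth,max_penwidth positive reals,
#'   \code{min_penwidth <= max_penwidth}.
#' @param show_virtual_endpoints add virtual start/end nodes marking where
#'   traces begin and end, for parity with conventional process maps. Off by
#'   default: the estimated chain itself has no such states.
#' @return A list of class \code{"render_options"}.
#' @export
render_options <- function(label_kind = NULL, decimals = 2L,
                           min_penwidth = 1, max_penwidth = 5,
                           show_virtual_endpoints = FALSE) {
  decimals <- as.integer(decimals)
  if (is.na(decimals) || decimals < 0) {
    stop("decimals must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(label_kind)) {
    label_kind <- match.arg(label_kind,
                            c("frequency", "probability", "difference"))
  }
  if (min_penwidth <= 0 || max_penwidth <= 0 || min_penwidth > max_penwidth) {
    stop("need 0 < min_penwidth <= max_penwidth", call. = FALSE)
  }
  structure(list(label_kind = label_kind, decimals = decimals,
                 min_penwidth = min_penwidth, max_penwidth = max_penwidth,
                 show_virtual_endpoints = show_virtual_endpoints),
            class = "render_options")
}

penwidths <- function(v, options) {
  if (length(v) == 0) return(numeric(0))
  rng <- range(v)
  if (rng[2] == rng[1]) {
    rep(options$max_penwidth, length(v))
  } else {
    options$min_penwidth + (options$max_penwidth - options$min_penwidth) *
      (v - rng[1]) / (rng[2] - rng[1])
  }
}

format_value <- function(v, kind, decimals) {
  if (kind == "frequency") {
    vapply(v, function(x) format(x, scientific = FALSE), character(1))
  } else {
    sprintf(paste0("%.", decimals, "f"), v)
  }
}

#' Emit a process map as Graphviz DOT text
#'
#' One node per state and one directed edge per stored pair; the edge label
#' is the frequency (for a [dfg()]) or the transition probability rounded to
#' \code{options$decimals} (for a [to_stochastic()] result), and flow
#' thickness follows the edge value. Output is deterministic: nodes and
#' edges are emitted in sorted order, so repeated calls are byte-identical.
#'
#' @param x a \code{"dfg"} or \code{"stochastic_dfg"} with a non-empty state
#'   set.
#' @param options a [render_options()].
#' @return A single string of DOT source.
#' @examples
#' path <- system.file("extdata", "hospital_log.csv", package = "dfgdiff")
#' cat(dfg_to_dot(dfg(read_event_log(path))))
#' @export
dfg_to_dot <- function(x, options = render_options()) {
  stopifnot(inherits(x, "dfg") || inherits(x, "stochastic_dfg"))
  if (length(x$states) == 0) {
    stop("cannot render an empty graph (no states)", call. = FALSE)
  }
  kind <- options$label_kind %||%
    if (inherits(x, "stochastic_dfg")) "probability" else "frequency"
  values <- if (inherits(x, "stochastic_dfg")) x$edges$prob else x$edges$freq
  labels <- format_value(values, kind, options$decimals)
  widths <- penwidths(values, options)
  lines <- c("digraph dfg {",
             sprintf("  // kind=%s", kind),
             "  rankdir=LR;",
             "  node [shape=box, style=rounded];",
             sprintf("  %s;", quote_dot(x$states)))
  lines <- c(lines, virtual_endpoint_lines(x, options))
  if (nrow(x$edges) > 0) {
    lines <- c(lines, sprintf(
      "  %s -> %s [label=%s, penwidth=%.3f];",
      quote_dot(x$edges$source), quote_dot(x$edges$target),
      quote_dot(labels), widths))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

# Dotted flows from a virtual start node into trace-initial states and from
# trace-final states into a virtual end node. Uses the fitted start/end
# counts when present, else falls back to in-degree-0 / out-degree-0 states.
virtual_endpoint_lines <- function(x, options) {
  if (!isTRUE(options$show_virtual_endpoints)) return(character(0))
  starts <- if (!is.null(x$initial)) names(x$initial) else
    setdiff(x$states, x$edges$target)
  ends <- if (!is.null(x$terminal)) names(x$terminal) else
    setdiff(x$states, x$edges$source)
  c('  "__start__" [label="start", shape=circle];',
    '  "__end__" [label="end", shape=doublecircle];',
    sprintf('  "__start__" -> %s [style=dotted];', quote_dot(sort(starts))),
    sprintf('  %s -> "__end__" [style=dotted];', quote_dot(sort(ends))))
}

#' Emit a difference process map as Graphviz DOT text
#'
#' Flows with positive difference are drawn solid, flows with negative
#' difference dashed; labels show the signed difference in fixed point
#' (leading minus for negatives) and thickness scales with the absolute
#' difference. The cut-off and orientation are recorded in a graph-level
#' comment. An empty difference renders as a valid graph with the known
#' states and no edges.
#'
#' @param diff a \code{"diff_dfg"} from [compare_dfg()].
#' @param options a [render_options()].
#' @return A single string of DOT source.
#' @export
diff_to_dot <- function(diff, options = render_options()) {
  stopifnot(inherits(diff, "diff_dfg"))
  labels <- format_value(diff$edges$diff, "difference", options$decimals)
  widths <- penwidths(abs(diff$edges$diff), options)
  lines <- c("digraph dfg_diff {",
             sprintf("  // kind=difference cutoff=%s minuend=%s subtrahend=%s",
                     format(diff$cutoff), quote_dot(diff$minuend),
                     quote_dot(diff$subtrahend)),
             "  rankdir=LR;",
             "  node [shape=box, style=rounded];")
  if (length(diff$states) > 0) {
    lines <- c(lines, sprintf("  %s;", quote_dot(diff$states)))
  }
  if (nrow(diff$edges) > 0) {
    lines <- c(lines, sprintf(
      "  %s -> %s [label=%s, style=%s, penwidth=%.3f];",
      quote_dot(diff$edges$source), quote_dot(diff$edges$target),
      quote_dot(labels),
      ifelse(diff$edges$diff < 0, "dashed", "solid"), widths))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}
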