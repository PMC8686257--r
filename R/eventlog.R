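#' Construct a validated event log
#'
#' An event log records executions of a process: every event ties a case
#' identifier, a state (activity) label, and an integer order giving the
#' event's position within its case. Optional per-event attributes (for
#' example a cohort marker such as \code{"Is Emergency"}) travel alongside
#' and are required to be constant within a case when used for splitting.
#'
#' Validation enforces: \code{order >= 1} and integer-valued; state labels
#' non-empty after trimming surrounding whitespace; within one case all order
#' values pairwise distinct. Order values need not be consecutive -- only the
#' relative order matters. Labels are compared exactly after trimming; no
#' case folding is applied. Single-event cases are legal; they simply
#' contribute no directly-follows pairs.
#'
#' @param case_id character (or coercible) vector of case identifiers.
#' @param state character vector of state labels; trimmed, must be non-empty.
#' @param order integer vector of within-case sequence positions, \code{>= 1}.
#' @param attributes optional data frame of per-event attribute columns,
#'   one row per event.
#' @param allow_ties if \code{TRUE}, duplicate (case, order) pairs are kept
#'   with a warning and broken stably by input row order instead of being
#'   rejected. Intended for messy real logs only.
#' @return An object of class \code{"event_log"}.
#' @seealso [read_event_log()], [traces()], [split_by_attribute()]
#' @examples
#' log <- event_log(case_id = c(1, 1, 1, 2, 2),
#'                  state   = c("a", "b", "c", "a", "c"),
#'                  order   = c(1, 2, 3, 1, 2))
#' traces(log)
#' @export
event_log <- function(case_id, state, order, attributes = NULL,
                      allow_ties = FALSE) {
  case_id <- as.character(case_id)
  state <- trimws(as.character(state))
  n <- length(case_id)
  if (length(state) != n || length(order) != n) {
    stop("case_id, state and order must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (!is.numeric(order) || anyNA(order) || any(order != floor(order))) {
      bad <- if (is.numeric(order)) which(is.na(order) | order != floor(order)) else seq_len(n)
      stop("order must be integer-valued (row ",
           paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
    }
    if (any(order < 1)) {
      stop("order must be >= 1 (row ",
           paste(utils::head(which(order < 1), 5), collapse = ", "), ")",
           call. = FALSE)
    }
    if (any(!nzchar(state)) || anyNA(state)) {
      stop("empty state label (row ",
           paste(utils::head(which(!nzchar(state) | is.na(state)), 5),
                 collapse = ", "), ")", call. = FALSE)
    }
    key <- paste(case_id, order, sep = "\x1f")
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      first <- match(key[dup], key)
      pairs <- paste0("case ", case_id[dup], " order ", order[dup],
                      " (rows ", first, " and ", dup, ")")
      if (allow_ties) {
        warning("duplicate (case, order) pairs kept with stable row-order ",
                "tie-break: ", paste(pairs, collapse = "; "), call. = FALSE)
      } else {
        stop("duplicate (case, order) pair: ",
             paste(utils::head(pairs, 5), collapse = "; "), call. = FALSE)
      }
    }
  }
  order <- as.integer(order)
  if (!is.null(attributes)) {
    attributes <- as.data.frame(attributes, stringsAsFactors = FALSE,
                                check.names = FALSE)
    if (nrow(attributes) != n) {
      stop("attributes must have one row per event", call. = FALSE)
    }
    attributes[] <- lapply(attributes, as.character)
  } else {
    attributes <- data.frame(row.names = seq_len(n))
  }
  if (n > 0) {
    per_case <- table(case_id)
    singletons <- names(per_case)[per_case == 1]
    if (length(singletons) > 0) {
      warning("single-event case(s) contribute no directly-follows pairs: ",
              paste(utils::head(singletons, 5), collapse = ", "),
              if (length(singletons) > 5) ", ...", call. = FALSE)
    }
  }
  structure(
    list(events = data.frame(case_id = case_id, state = state, order = order,
                             stringsAsFactors = FALSE),
         attributes = attributes),
    class = "event_log")
}

#' Read an event log from a delimited text file
#'
#' The file must have a header row. The column map names which columns play
#' the case / activity / order roles; additional columns listed in
#' \code{attribute_columns} are carried as per-event attributes and all other
#' columns are ignored.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param column_map named character vector with entries \code{case},
#'   \code{activity} and \code{order} giving the corresponding column names.
#' @param attribute_columns optional character vector of extra columns to
#'   carry as attributes.
#' @param delimiter field delimiter, default comma.
#' @inheritParams event_log
#' @return An [event_log()].
#' @examples
#' path <- system.file("extdata", "hospital_log.csv", package = "dfgdiff")
#' log <- read_event_log(path, attribute_columns = "Is Emergency")
#' log
#' @export
read_event_log <- function(path,
                           column_map = c(case = "Case ID",
                                          activity = "Activity",
                                          order = "Order"),
                           attribute_columns = NULL,
                           delimiter = ",",
                           allow_ties = FALSE) {
  if (!file.exists(path)) {
    stop("event-log file not found: ", path, call. = FALSE)
  }
  for (role in c("case", "activity", "order")) {
    if (!role %in% names(column_map)) {
      stop("column_map must name a ", sQuote(role), " column", call. = FALSE)
    }
  }
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  needed <- c(unname(column_map[c("case", "activity", "order")]),
              attribute_columns)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("column(s) not present in ", path, ": ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  order_raw <- df[[column_map[["order"]]]]
  ok <- grepl("^\\s*[0-9]+\\s*$", order_raw)
  if (any(!ok)) {
    stop("non-integer order value at data row ",
         paste(utils::head(which(!ok), 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  attrs <- if (length(attribute_columns) > 0) df[attribute_columns] else NULL
  event_log(case_id = df[[column_map[["case"]]]],
            state = df[[column_map[["activity"]]]],
            order = as.integer(order_raw),
            attributes = attrs,
            allow_ties = allow_ties)
}

#' Write an event log to a delimited text file
#'
#' Inverse of [read_event_log()]: a written log re-read with the same column
#' map reproduces the same events, traces and attributes.
#'
#' @param log an [event_log()].
#' @param path output file path.
#' @inheritParams read_event_log
#' @return \code{path}, invisibly.
#' @export
write_event_log <- function(log, path,
                            column_map = c(case = "Case ID",
                                           activity = "Activity",
                                           order = "Order"),
                            delimiter = ",") {
  stopifnot(inherits(log, "event_log"))
  out <- data.frame(log$events$case_id, log$events$state, log$events$order,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(column_map[c("case", "activity", "order")])
  if (ncol(log$attributes) > 0) {
    out <- cbind(out, log$attributes)
  }
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE, qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Distinct case identifiers of an event log
#' @param log an [event_log()].
#' @return Sorted character vector of case identifiers.
#' @export
case_ids <- function(log) {
  stopifnot(inherits(log, "event_log"))
  sort(unique(log$events$case_id))
}

#' Distinct state labels
#'
#' @param x an [event_log()], [dfg()] or derived object.
#' @return Sorted character vector of state labels. For directly-follows
#'   graphs this is the union of sources and targets of stored pairs, so a
#'   log of single-event traces yields a graph with no states.
#' @export
states <- function(x) UseMethod("states")

#' @export
states.event_log <- function(x) sort(unique(x$events$state))

#' @export
states.dfg <- function(x) x$states

#' @export
states.stochastic_dfg <- function(x) x$states

#' @export
states.diff_dfg <- function(x) x$states

#' Per-case traces
#'
#' Materialises the ordered sequence of state labels visited by each case,
#' sorting events by ascending order index within the case.
#'
#' @param log an [event_log()].
#' @return Named list (one element per case, names = case ids, sorted) of
#'   character vectors of state labels.
#' @export
traces <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  ids <- sort(unique(ev$case_id))
  out <- lapply(ids, function(cid) {
    rows <- which(ev$case_id == cid)
    rows <- rows[order(ev$order[rows])]   # stable: ties keep file row order
    ev$state[rows]
  })
  names(out) <- ids
  out
}

#' Split an event log into two cohorts by a case-level attribute
#'
#' Cohort membership is a property of the case, not of individual events:
#' every event of a case must carry the same value for the splitting
#' attribute, otherwise the case is reported as inconsistent. The two
#' returned logs partition the cases -- their case-id sets are disjoint and
#' their union is the input's.
#'
#' @param log an [event_log()] carrying the attribute.
#' @param attribute attribute (column) name to split on.
#' @param value attribute value selecting the first cohort.
#' @return A list with elements \code{matching} (cases whose attribute equals
#'   \code{value}) and \code{remainder} (all other cases), both event logs.
#' @examples
#' path <- system.file("extdata", "hospital_log.csv", package = "dfgdiff")
#' log <- read_event_log(path, attribute_columns = "Is Emergency")
#' cohorts <- split_by_attribute(log, "Is Emergency", "True")
#' case_ids(cohorts$matching)
#' @export
split_by_attribute <- function(log, attribute, value) {
  stopifnot(inherits(log, "event_log"))
  if (!attribute %in% names(log$attributes)) {
    stop("attribute ", sQuote(attribute), " not present in the log",
         call. = FALSE)
  }
  vals <- log$attributes[[attribute]]
  by_case <- split(vals, log$events$case_id)
  n_distinct <- vapply(by_case, function(v) length(unique(v)), integer(1))
  if (any(n_distinct > 1)) {
    stop("inconsistent ", sQuote(attribute), " within case(s): ",
         paste(utils::head(names(by_case)[n_distinct > 1], 5), collapse = ", "),
         call. = FALSE)
  }
  case_value <- vapply(by_case, `[`, "", 1)
  match_ids <- names(case_value)[case_value == value]
  in_match <- log$events$case_id %in% match_ids
  list(matching = subset_events(log, in_match),
       remainder = subset_events(log, !in_match))
}

# Row-subset of an event log (keeps whole rows; used for case subsets).
subset_events <- function(log, keep) {
  event_log(case_id = log$events$case_id[keep],
            state = log$events$state[keep],
            order = log$events$order[keep],
            attributes = log$attributes[keep, , drop = FALSE])
}

#' Stratified random sample of whole cases
#'
#' Draws cases uniformly without replacement within each stratum. Whole cases
#' are kept or dropped together -- traces are never truncated. Sampling is
#' deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param log an [event_log()].
#' @param stratum_of named character vector mapping every case id in the log
#'   to its stratum label.
#' @param per_stratum_counts named integer vector: how many cases to draw
#'   from each stratum. Every named stratum must occur in \code{stratum_of},
#'   and no count may exceed the stratum size.
#' @param seed integer seed.
#' @return An [event_log()] with exactly \code{sum(per_stratum_counts)} cases.
#' @export
stratified_sample <- function(log, stratum_of, per_stratum_counts, seed) {
  stopifnot(inherits(log, "event_log"))
  ids <- case_ids(log)
  unassigned <- setdiff(ids, names(stratum_of))
  if (length(unassigned) > 0) {
    stop("case(s) without a stratum: ",
         paste(utils::head(unassigned, 5), collapse = ", "), call. = FALSE)
  }
  strata <- split(ids, unname(stratum_of[ids]))
  chosen <- with_seed(seed, {
    unlist(lapply(sort(names(per_stratum_counts)), function(st) {
      k <- per_stratum_counts[[st]]
      if (!st %in% names(strata)) {
        stop("unknown stratum ", sQuote(st), call. = FALSE)
      }
      pool <- sort(strata[[st]])
      if (k > length(pool)) {
        stop("requested ", k, " cases from stratum ", sQuote(st),
             " which has only ", length(pool), call. = FALSE)
      }
      pool[sample.int(length(pool), k)]
    }), use.names = FALSE)
  })
  subset_events(log, log$events$case_id %in% chosen)
}

#' @export
print.event_log <- function(x, ...) {
  cat("Event log: ", nrow(x$events), " events, ",
      length(unique(x$events$case_id)), " cases, ",
      length(unique(x$events$state)), " states\n", sep = "")
  if (ncol(x$attributes) > 0) {
    cat("Attributes: ", paste(names(x$attributes), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.event_log <- function(object, ...) {
  tr <- traces(object)
  lens <- lengths(tr)
  structure(list(n_events = nrow(object$events), n_cases = length(tr),
                 states = states(object), trace_lengths = summary(lens),
                 n_pairs = sum(pmax(lens - 1L, 0L)),
                 attributes = names(object$attributes)),
            class = "summary.event_log")
}

#' @export
print.summary.event_log <- function(x, ...) {
  cat("Event log summary\n")
  cat("  events:", x$n_events, " cases:", x$n_cases, "\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  directly-follows pairs:", x$n_pairs, "\n")
  cat("  trace length:\n")
  print(x$trace_lengths)
  invisible(x)
}
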