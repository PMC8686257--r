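# Shared fixtures and independent oracles.

toy_log_path <- function() {
  system.file("extdata", "hospital_log.csv", package = "dfgdiff")
}

toy_log <- function() {
  read_event_log(toy_log_path(), attribute_columns = "Is Emergency")
}

# Independent brute-force oracle for directly-follows counting: scans each
# trace with a sliding window of width 2 and tallies pairs in a plain named
# vector. Deliberately shares no code with dfg().
oracle_dfg_counts <- function(trace_list) {
  counts <- numeric(0)
  for (tr in trace_list) {
    if (length(tr) < 2) next
    for (i in seq_len(length(tr) - 1)) {
      key <- paste(tr[i], tr[i + 1], sep = "\x1f")
      counts[key] <- ifelse(is.na(counts[key]), 1, counts[key] + 1)
    }
  }
  if (length(counts) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      freq = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(counts), "\x1f", fixed = TRUE)
  df <- data.frame(source = vapply(parts, `[`, "", 1),
                   target = vapply(parts, `[`, "", 2),
                   freq = as.integer(unname(counts)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random event log over at most n_states labels with trace lengths 1..8.
random_log <- function(n_cases, n_states, seed) {
  with_seed_helper(seed, {
    labels <- paste0("s", seq_len(n_states))
    tr <- lapply(seq_len(n_cases), function(i) {
      sample(labels, sample.int(8, 1), replace = TRUE)
    })
    lens <- lengths(tr)
    suppressWarnings(event_log(
      case_id = rep(sprintf("case%02d", seq_len(n_cases)), lens),
      state = unlist(tr, use.names = FALSE),
      order = unlist(lapply(lens, seq_len), use.names = FALSE)))
  })
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Grammar-level structural check of emitted DOT text: every line must be a
# graph header/footer, comment, attribute statement, quoted node statement or
# quoted edge statement, with balanced braces.
expect_valid_dot <- function(txt) {
  expect_type(txt, "character")
  expect_length(txt, 1)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  expect_match(lines[1], "^digraph [A-Za-z_][A-Za-z0-9_]* \\{$")
  expect_identical(lines[length(lines)], "}")
  qs <- '"(?:[^"\\\\]|\\\\.)*"'
  patterns <- c(
    comment = "^  // .*$",
    attr = "^  (rankdir=[A-Za-z]+|node \\[[^]]*\\]);$",
    node = paste0("^  ", qs, "( \\[[^]]*\\])?;$"),
    edge = paste0("^  ", qs, " -> ", qs, " \\[[^]]*\\];$"))
  body <- lines[-c(1, length(lines))]
  for (line in body) {
    ok <- any(vapply(patterns, function(p) grepl(p, line, perl = TRUE),
                     logical(1)))
    expect_true(ok, label = paste("DOT line parses:", line))
  }
  n_open <- lengths(regmatches(txt, gregexpr("{", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr("}", txt, fixed = TRUE)))
  expect_equal(n_open, n_close)
  invisible(txt)
}

sample_seeded <- function(max, seed) {
  with_seed_helper(seed, sample.int(max, 1))
}

# Probability looked up with missing-edge-as-zero convention.
prob_of <- function(sdfg, source, target) {
  hit <- sdfg$edges$source == source & sdfg$edges$target == target
  if (any(hit)) sdfg$edges$prob[hit] else 0
}

diff_of <- function(diff, source, target) {
  hit <- diff$edges$source == source & diff$edges$target == target
  if (any(hit)) diff$edges$diff[hit] else NA_real_
}
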