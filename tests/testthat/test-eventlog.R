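test_that("the printed worked example parses into 9 events, 2 cases, 5 states", {
  log <- toy_log()
  expect_equal(nrow(log$events), 9L)
  expect_equal(case_ids(log), c("1", "2"))
  expect_equal(states(log), c("op", "rj", "rp", "uj", "vp"))
  tr <- traces(log)
  expect_equal(tr[["1"]], c("rp", "rj", "vp", "uj", "op", "uj"))
  expect_equal(tr[["2"]], c("rp", "rj", "op"))
})

test_that("an empty file with only a header yields an empty log", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines('"Case ID","Activity","Order"', path)
  log <- read_event_log(path)
  expect_equal(nrow(log$events), 0L)
  expect_length(case_ids(log), 0)
  expect_length(traces(log), 0)
})

test_that("reading rejects bad inputs with informative errors", {
  expect_error(read_event_log(file.path(tempdir(), "no-such-file.csv")),
               "no-such-file.csv")
  expect_error(read_event_log(toy_log_path(),
                              column_map = c(case = "Case ID",
                                             activity = "Nope",
                                             order = "Order")),
               "Nope")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"Case ID","Activity","Order"',
               '"1","a","1"', '"1","b","two"'), path)
  expect_error(read_event_log(path), "row 2")
})

test_that("duplicate (case, order) pairs are a hard error reporting both rows", {
  expect_error(event_log(case_id = c("1", "1", "1"),
                         state = c("a", "b", "c"),
                         order = c(1, 2, 2)),
               "rows 2 and 3")
  # --allow-ties relaxation: stable tie-break by row order, with a warning
  expect_warning(
    log <- event_log(case_id = c("1", "1", "1"), state = c("a", "b", "c"),
                     order = c(1, 2, 2), allow_ties = TRUE),
    "tie-break")
  expect_equal(traces(log)[["1"]], c("a", "b", "c"))
})

test_that("validation enforces order >= 1 and non-empty trimmed labels", {
  expect_error(event_log("1", "a", 0), "order")
  expect_error(event_log("1", "a", 1.5), "integer")
  expect_error(event_log("1", "   ", 1), "empty state")
  log <- suppressWarnings(event_log("1", "  rp  ", 1))
  expect_equal(log$events$state, "rp")
})

test_that("order values need not be consecutive; only relative order matters", {
  log <- event_log(case_id = c("c", "c", "c"), state = c("a", "b", "d"),
                   order = c(1, 3, 7))
  expect_equal(traces(log)[["c"]], c("a", "b", "d"))
})

test_that("single-event cases are legal but warn (zero pairs)", {
  expect_warning(log <- event_log("solo", "a", 1), "single-event")
  expect_equal(lengths(traces(log)), c(solo = 1L))
  expect_equal(total_pair_count(dfg(log)), 0)
})

test_that("splitting on a cohort attribute partitions the cases", {
  log <- toy_log()
  cohorts <- split_by_attribute(log, "Is Emergency", "True")
  expect_equal(case_ids(cohorts$matching), "2")
  expect_equal(case_ids(cohorts$remainder), "1")

  # vacuous and complement splits
  none <- split_by_attribute(log, "Is Emergency", "Maybe")
  expect_length(case_ids(none$matching), 0)
  expect_equal(case_ids(none$remainder), case_ids(log))
  all_true <- suppressWarnings(
    split_by_attribute(log, "Is Emergency", "True"))
  expect_equal(sort(c(case_ids(all_true$matching),
                      case_ids(all_true$remainder))), case_ids(log))

  expect_error(split_by_attribute(log, "No Such Attr", "x"), "No Such Attr")
})

test_that("a case with inconsistent attribute values is reported by id", {
  log <- event_log(case_id = c("1", "1"), state = c("a", "b"), order = 1:2,
                   attributes = data.frame(grp = c("x", "y")))
  expect_error(split_by_attribute(log, "grp", "x"), "case.*1")
})

test_that("split partition property holds on random logs", {
  for (seed in 1:10) {
    log <- random_log(n_cases = 12, n_states = 4, seed = seed)
    grp <- with_seed_helper(seed + 100, {
      per_case <- sample(c("x", "y"), 12, replace = TRUE)
      names(per_case) <- sprintf("case%02d", 1:12)
      per_case
    })
    log$attributes <- data.frame(grp = unname(grp[log$events$case_id]),
                                 stringsAsFactors = FALSE)
    cohorts <- suppressWarnings(split_by_attribute(log, "grp", "x"))
    ids_a <- case_ids(cohorts$matching)
    ids_b <- case_ids(cohorts$remainder)
    expect_length(intersect(ids_a, ids_b), 0)
    expect_setequal(c(ids_a, ids_b), case_ids(log))
  }
})

test_that("write/read round trip preserves events, traces and attributes", {
  log <- toy_log()
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, path)
  back <- read_event_log(path, attribute_columns = "Is Emergency")
  expect_equal(back$events, log$events)
  expect_equal(back$attributes$`Is Emergency`, log$attributes$`Is Emergency`)
  expect_equal(traces(back), traces(log))

  # empty log round trips to a header-only file
  empty <- event_log(character(0), character(0), integer(0))
  write_event_log(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_event_log(path)$events), 0L)
})

test_that("stratified sampling draws whole cases, per-stratum, reproducibly", {
  log <- random_log(n_cases = 10, n_states = 3, seed = 7)
  ids <- case_ids(log)
  stratum <- setNames(rep(c("wk", "we"), c(8, 2)), ids)

  # exhaustive sample returns everything
  all_of_it <- suppressWarnings(
    stratified_sample(log, stratum, c(wk = 8, we = 2), seed = 1))
  expect_setequal(case_ids(all_of_it), ids)

  # strata of sizes 8 and 2, counts 4 and 1
  samp <- suppressWarnings(
    stratified_sample(log, stratum, c(wk = 4, we = 1), seed = 42))
  got <- case_ids(samp)
  expect_length(got, 5)
  expect_equal(sum(stratum[got] == "wk"), 4)
  expect_equal(sum(stratum[got] == "we"), 1)
  # whole cases: every sampled case keeps its full trace
  expect_equal(traces(samp), traces(log)[sort(got)])

  # determinism under a fixed seed
  again <- suppressWarnings(
    stratified_sample(log, stratum, c(wk = 4, we = 1), seed = 42))
  expect_identical(case_ids(again), got)

  expect_error(stratified_sample(log, stratum, c(wk = 9), seed = 1), "only 8")
  expect_error(stratified_sample(log, stratum, c(holiday = 1), seed = 1),
               "unknown stratum")
})

test_that("trace-length identity: sum(len - 1) equals the DFG pair total", {
  log <- toy_log()
  lens <- lengths(traces(log))
  expect_equal(sum(lens - 1L), 7L)
  expect_equal(total_pair_count(dfg(log)), sum(lens - 1L))
})
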