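# Internal helpers shared across modules.

# Evaluate `code` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-case seed from a root seed so the stream for case i does not
# depend on how many cases follow it. Kept strictly below 2^31 - 1.
derive_case_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + i * 1046527) %% 2147483647)
}

# Accept a cut-off either as a fraction ("0.2") or a percentage ("20%");
# always return the fraction.
parse_cutoff <- function(x) {
  if (is.numeric(x)) {
    cutoff <- x
  } else {
    x <- trimws(as.character(x))
    if (grepl("%$", x)) {
      cutoff <- suppressWarnings(as.numeric(sub("%$", "", x))) / 100
    } else {
      cutoff <- suppressWarnings(as.numeric(x))
    }
  }
  if (length(cutoff) != 1L || is.na(cutoff)) {
    stop("cannot interpret cutoff ", sQuote(x), call. = FALSE)
  }
  check_cutoff(cutoff)
  cutoff
}

check_cutoff <- function(cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff >= 1) {
    stop("cutoff must lie in [0, 1), got ", format(cutoff), call. = FALSE)
  }
  invisible(cutoff)
}

quote_dot <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}
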