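---
title: "Comparing process variants with stochastic directly-follows graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing process variants with stochastic directly-follows graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfgdiff)
```

## The problem

Healthcare processes run in variants: emergency versus planned admissions,
users who consult a decision-support warning versus users who dismiss it.
Each variant (a *cohort*) leaves traces in an event log — per case, the
ordered sequence of states the process visited. Comparing cohorts by
activity frequencies or durations misses a question that matters clinically:
*given the process is in state a, how differently do the two cohorts move
on from it?* That is a question about transition probabilities, i.e. about
the first-order Markov chain each cohort's log implies.

`dfgdiff` answers it in three deterministic steps:

1. **Count.** For each cohort, fit a directly-follows graph (DFG): for every
   ordered state pair $(a, b)$, count the positions, across all traces,
   where $a$ is immediately followed by $b$ within the same case
   ($\Psi(a,b)$). Pairs never span two cases, and self-loops count like any
   other pair.
2. **Normalise.** Divide each count by the total outgoing count of its
   source state:
   $\Psi'(a,b) = \Psi(a,b) \,/\, \sum_x \Psi(a,x)$.
   This is the maximum-likelihood estimate of the chain's transition matrix;
   each observed source row sums to one, and states with no observed
   successor (trace-terminal states) simply have no row.
3. **Contrast.** For every pair stored in either cohort's stochastic DFG,
   take the signed difference $d(a,b) = \Psi'_A(a,b) - \Psi'_B(a,b)$, with a
   pair missing from one cohort contributing probability 0, and keep the
   pair iff $|d| > c$ for a cut-off $c \in [0, 1)$.

The result is rendered as a *difference process map*: one node per state,
solid edges where cohort A transitions more often, dashed edges where
cohort B does, thickness scaled by $|d|$.

## Model and assumptions

The estimate in step 2 is exactly a first-order Markov chain fitted by
maximum likelihood: it assumes the next state depends only on the current
state, not on the path so far, and that transition probabilities are
homogeneous across a cohort and over time. Event logs violate these
assumptions to varying degrees; the fitted object should be read as a
cohort-level summary of one-step behaviour, not as a generative model of
individual careers. Ordering within a case comes from an explicit integer
order column — values need not be consecutive, only their relative order is
used. There is no timestamp handling: converting timestamps to order
indices is upstream preprocessing, out of scope here.

## Parameters that matter

* **Cut-off $c$** (default 0.2 in the CLI; `compare_dfg()` defaults to 0).
  A deterministic threshold on the probability scale, in the tradition of
  edge-filtering discovery algorithms — *not* a significance test. The
  strict inequality means ties at the cut-off are dropped, so `cutoff = 0`
  keeps every non-zero difference and the self-comparison is always empty.
  Both `0.2` and `"20%"` are accepted; the internal value is always the
  fraction.
* **Orientation.** Differences are first-argument-minus-second, and the
  minuend/subtrahend labels travel with the result (and into the CSV/DOT
  metadata), because the sign is the substance of the comparison.
* **Missing pairs count as zero.** When a pair occurs in one cohort only,
  the other cohort contributes probability 0. This is the only convention
  that keeps the comparison antisymmetric and bounded in $[-1, 1]$.
* **No virtual start/end states by default.** The estimated chain contains
  only observed activities; terminal states just lack outgoing rows.
  `render_options(show_virtual_endpoints = TRUE)` adds dotted start/end
  markers for visual parity with conventional process maps.

## Worked example

The package ships a nine-row excerpt of a hospital log over five
activities — register patient (rp), read journal (rj), visit patient (vp),
update journal (uj), operate (op) — with an `Is Emergency` cohort marker:

```{r}
log <- read_event_log(system.file("extdata", "hospital_log.csv", package = "dfgdiff"),
                      attribute_columns = "Is Emergency")
traces(log)
d <- dfg(log)
d
to_stochastic(d)$edges
```

`rp` is followed by `rj` twice (once per case), so $\Psi(rp, rj) = 2$; `rj`
branches half/half to `vp` and `op` after normalisation. Splitting on the
cohort marker and contrasting the two estimated chains:

```{r}
cohorts <- split_by_attribute(log, "Is Emergency", "True")
diff <- compare_dfg(to_stochastic(dfg(cohorts$matching)),
                    to_stochastic(dfg(cohorts$remainder)),
                    cutoff = 0, labels = c("emergency", "planned"))
diff
cat(diff_to_dot(diff))
```

## The simulator and what it does (not) emulate

`markov_chain_spec()` + `generate_cohort_log()` generate two-cohort logs
from explicit chains so the whole pipeline is testable end to end, and so
estimator consistency can be checked against known truth. Design choices:

* **Termination is modelled with terminal rows** (absorbing stops) rather
  than an artificial END activity, so generated logs contain only real
  activity labels. `max_trace_length` (default 50) guards against
  non-terminating chains; truncated traces are flagged and counted, and a
  warning reports the count.
* **One root seed drives an arithmetically derived per-case stream**, so
  enlarging the second cohort never changes the first cohort's traces, and
  a fixed seed gives byte-identical CSV output.
* `running_example_preset()` encodes the emergency / non-emergency hospital
  narrative over \{rp, rj, vp, uj, op\}. The probabilities are this
  package's own illustrative choice — the narrative fixes only the shape:
  both cohorts always start at `rp`; the emergency chain operates directly
  after registration 30% of the time, otherwise reads the journal and then
  mostly operates (75%) without ever visiting; the non-emergency chain
  reads, visits (80%), updates the journal (90%) and loops back to re-read
  it 40% of the time before operating. With these matrices the
  emergency-minus-planned difference on (rp, op) is $+0.3$, comfortably
  above the 0.2 cut-off used in the examples.

What the simulator does **not** emulate about real logs: heterogeneous
case-mix within a cohort, time-varying or history-dependent transition
behaviour, noise in activity labels, and incomplete traces. Green tests on
simulated data therefore certify the *estimator and its plumbing* — not
that a real process is first-order Markov.

## Numerical choices and degenerate inputs

* Row-sum checks on probability vectors and stochastic rows use an absolute
  tolerance of $10^{-9}$; normalised rows are exact up to floating division.
* Duplicate (case, order) pairs are a hard error (silent reordering would
  corrupt the counts); `allow_ties = TRUE` opts into a stable file-order
  tie-break with a warning, for messy real logs.
* Single-event cases are legal, contribute zero directly-follows pairs, and
  produce a warning rather than an error. An empty log yields an empty
  graph; an empty difference renders as a valid DOT graph with no edges.
* All serialized edge lists and DOT output are sorted lexicographically by
  (source, target), so every artifact is byte-stable across runs.
* Pen widths scale affinely from `min_penwidth` to `max_penwidth` over the
  observed value range (absolute differences for difference maps); a
  degenerate range (all edges equal) maps every edge to `max_penwidth`.
  Labels use fixed-point rounding, two decimals by default.
* Stratified case sampling draws whole cases without replacement within
  each stratum, iterating strata in sorted order under one seed, so results
  are reproducible and never contain partial traces.

## Problem sizes used in the test suite

The property suites run the counting oracle comparison on 200 random logs
of up to 20 cases over up to 10 states, and parameter recovery draws 10,000
traces per cohort from the running-example preset, where the estimated
transition matrices match the generating ones to within 0.02 in maximum
absolute deviation — the scale of the binomial standard error at the
smallest per-state visit counts involved ($\approx 0.005$, so 0.02 is about
four standard errors). The end-to-end null check compares two cohorts of
5,000 traces drawn from one identical chain at cutoff 0 and finds no
difference above 0.05.

## Known limitations

* First-order only: no higher-order or hidden-state Markov models.
* The cut-off is not a hypothesis test; with small cohorts, sampling noise
  alone can exceed it. Inspect cohort sizes (the CLI refuses empty cohorts
  and logs case counts) before reading meaning into a difference map.
* No distance between whole chains is defined — the output is per-edge.
* No timestamp parsing, XES ingestion, or performance (duration) overlays.
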