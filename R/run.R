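#' Run an exact stochastic simulation
#'
#' The classic exact SSA loop: draw a waiting time `tau ~ Exponential(total
#' propensity)`, advance the clock, select a channel with probability
#' proportional to its propensity, fire it, and refresh the propensities of
#' the channels that depend on the touched state.  Timed events interleave
#' exactly: when `t + tau` crosses the next event time the clock advances to
#' the event, the event is applied, and `tau` is redrawn (valid by
#' memorylessness of the exponential clock).  The run stops at `t_end`, when
#' the requested number of firings is reached, or when no channel has
#' positive propensity and no events remain.
#'
#' @param x A `polysim_model` (a fresh system is compiled, so replicate runs
#'   are independent) or a `reaction_system` (state is advanced in place).
#' @param t_end End time in seconds.
#' @param seed Integer seed; identical (model, seed, solver) gives an
#'   identical trajectory bit for bit.
#' @param solver Reaction-selection structure: `"direct"` (linear scan,
#'   O(R) per event), `"tree"` (binary partial-sum tree, O(log R)) or
#'   `"cr"` (composition-rejection, O(1), the default).
#' @param log_period Sampling period of the trajectory, in seconds.
#' @param observables Character vector of species to log; defaults to the
#'   model's `Observe` records, or to all free chemicals if none.
#' @param max_events Stop after this many firings (0 = unlimited).
#' @param check_every If positive, audit the dependency-graph propensities
#'   and all filters against a scratch recomputation every so many firings
#'   (slow; for validation).
#' @return A `trajectory`: data frame of logged counts (column 1 `time`)
#'   with attributes `event_count`, `t_final`, `seed` and `solver`.
#'   Rows are logged every `log_period` while the system is active; once it
#'   goes permanently quiet the state is constant and a single closing row
#'   at `t_end` stands in for the remaining periods.  `t_final` is the time
#'   of the last firing (or event), which for run-to-completion systems is
#'   the exact completion time.
#' @export
#' @examples
#' m <- build_n_cascade(10, total_events = 1000)
#' tr <- run_simulation(m, t_end = 100, seed = 1, solver = "direct")
#' attr(tr, "event_count")  # exactly 1000
run_simulation <- function(x, t_end, seed = 1L, solver = c("cr", "tree", "direct"),
                           log_period = 1, observables = NULL, max_events = 0,
                           check_every = 0) {
  solver <- match.arg(solver)
  system <- as_system(x, seed = seed)
  if (is.null(observables)) {
    observables <- model_observables(system$model)
    if (length(observables) == 0L) {
      cts <- eng_counts(system$engine)
      observables <- names(cts$free)
    }
  }
  res <- eng_run(system$engine, t_end, seed, solver, log_period,
                 observables, max_events, check_every)
  df <- data.frame(time = res$time, res$counts, check.names = FALSE)
  structure(df,
            class = c("trajectory", "data.frame"),
            event_count = res$event_count,
            t_final = res$t_final,
            seed = seed, solver = solver)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x), " log points, ",
      format(attr(x, "event_count"), big.mark = ","), " firings, solver '",
      attr(x, "solver"), "', seed ", attr(x, "seed"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., log = "") {
  obs <- setdiff(names(x), "time")
  graphics::matplot(x$time, as.matrix(x[obs]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "molecules", log = log, ...)
  graphics::legend("topleft", legend = obs, col = seq_along(obs), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Number of reaction firings in a trajectory
#'
#' @param trajectory A [run_simulation()] result.
#' @return Numeric scalar.
#' @export
event_count <- function(trajectory) attr(trajectory, "event_count")

#' Sample an exponential waiting time by inversion
#'
#' `tau = -log(u) / total`: the waiting time to the next reaction when the
#' summed propensity is `total` and `u` is uniform on (0, 1).
#'
#' @param total Total propensity (> 0).
#' @param u Uniform deviate in (0, 1).
#' @return Waiting time in seconds.
#' @export
#' @examples
#' waiting_time_sample(2, exp(-1))  # 0.5
waiting_time_sample <- function(total, u) {
  if (any(total <= 0)) stop("no reaction: total propensity must be positive", call. = FALSE)
  stopifnot(all(u > 0), all(u < 1))
  -log(u) / total
}

#' Select a reaction channel with the direct method
#'
#' Linear scan over the propensity vector: returns the smallest index whose
#' cumulative sum reaches `u * sum(entries)` (ties resolved by the first
#' channel reaching the threshold).
#'
#' @param entries Non-negative propensity vector.
#' @param u Uniform deviate in \[0, 1).
#' @return 1-based channel index, or `NA` if all entries are zero.
#' @export
#' @examples
#' select_direct(c(1, 2, 3), 0.5)  # threshold 3.0 -> channel 2
select_direct <- function(entries, u) {
  cpp_select_direct(as.numeric(entries), u)
}

#' Select a reaction channel with the binary partial-sum tree
#'
#' Descends a binary tree of partial sums; distributionally identical to
#' [select_direct()] but O(log R) per draw.
#'
#' @inheritParams select_direct
#' @return 1-based channel index, or `NA` if all entries are zero.
#' @export
select_tree <- function(entries, u) {
  cpp_select_tree(as.numeric(entries), u)
}

#' Draw repeated channel selections under a given strategy
#'
#' Uses the same selection structures as the simulation loop.  For
#' `"direct"` and `"tree"` each draw consumes one uniform; the
#' composition-rejection strategy (`"cr"`) groups channels by the binary
#' exponent of their propensity (a channel with propensity a belongs to the
#' group with exponent `floor(log2 a)`), selects a group by composition and
#' a member by rejection, and so consumes a variable number of uniforms.
#'
#' @param entries Non-negative propensity vector.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param strategy `"direct"`, `"tree"` or `"cr"`.
#' @return Integer vector of 1-based channel indices.
#' @export
sample_selections <- function(entries, n, seed, strategy = c("direct", "tree", "cr")) {
  strategy <- match.arg(strategy)
  cpp_sample_selections(as.numeric(entries), n, seed, strategy)
}

#' Composition-rejection group exponent of a propensity
#'
#' @param a Positive propensity.
#' @return Integer g with `a` in `[2^g, 2^(g+1))`; negative exponents are
#'   allowed (e.g. 0.6 belongs to g = -1).
#' @export
cr_group_exponent <- function(a) {
  vapply(a, cpp_cr_exponent, integer(1))
}
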