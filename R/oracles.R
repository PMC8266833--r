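# Analytic and distributional oracles.  Every oracle here is a closed form
# or a standard statistical test, independent of the engine code paths it is
# used to check.

#' Expected transit time through a linear cascade
#'
#' A molecule crossing n first-order stages of rate `rate_per_stage` waits
#' an exponential time at each, so its transit time is Erlang(n, rate) with
#' mean `n / rate`.
#'
#' @param n_stages Number of stages (>= 1).
#' @param rate_per_stage Rate of each stage (> 0, 1/s).
#' @return Mean transit time in seconds.
#' @export
#' @examples
#' erlang_transit_mean(10, 1)  # 10
erlang_transit_mean <- function(n_stages, rate_per_stage) {
  if (any(n_stages < 1) || any(rate_per_stage <= 0))
    stop("need n_stages >= 1 and rate_per_stage > 0", call. = FALSE)
  n_stages / rate_per_stage
}

#' Mean speed of a sequential per-position cycle
#'
#' A polymerase advancing one position per completed cycle of sequential
#' exponential steps with rates `k_i` moves at `1 / sum(1/k_i)` positions
#' per second.  Note that with steps 10-100x faster than the limiting one,
#' the cycle speed is 10-25% below the limiting-step rate: a "50 nt/s"
#' translocation-limited cycle with 500 /s polymerization and ~1000 /s
#' loading advances at ~43.5 nt/s.
#'
#' @param step_rates Positive rates of the steps in one cycle (1/s).
#' @return Positions per second.
#' @export
#' @examples
#' elongation_speed_oracle(c(50, 500, 1000))  # 43.478
elongation_speed_oracle <- function(step_rates) {
  if (length(step_rates) == 0L) stop("empty rate list", call. = FALSE)
  if (any(step_rates <= 0)) stop("all step rates must be positive", call. = FALSE)
  1 / sum(1 / step_rates)
}

#' Mean interval between lagging-strand polymerase recruitments
#'
#' With Okazaki fragments of `fragment_bp` base pairs and a fork advancing
#' at `fork_speed_bps`, a new polymerase is recruited every
#' `fragment_bp / fork_speed_bps` seconds (1.33 s at 1000 bp and 750 bp/s).
#'
#' @param fragment_bp Okazaki fragment length (bp, > 0).
#' @param fork_speed_bps Fork speed (bp/s, > 0).
#' @return Interval in seconds.
#' @export
okazaki_recruitment_interval <- function(fragment_bp = 1000, fork_speed_bps = 750) {
  if (any(fragment_bp <= 0) || any(fork_speed_bps <= 0))
    stop("fragment length and fork speed must be positive", call. = FALSE)
  fragment_bp / fork_speed_bps
}

#' Recruitment balance of the replication fork
#'
#' The product `|DNAP_free| * r_recruitment`, i.e. the total recruitment
#' propensity of the lagging strand; the fork is balanced when it equals
#' the reciprocal of the recruitment interval, 3/4 per second.
#'
#' @param dnap_free Free DNA-polymerase count (>= 0).
#' @param recruitment_rate Per-polymerase recruitment rate (1/s, >= 0).
#' @return Total propensity (1/s).
#' @export
#' @examples
#' recruitment_balance(7.5, 0.1)  # 0.75 = 1 / 1.333 s
recruitment_balance <- function(dnap_free, recruitment_rate) {
  if (any(dnap_free < 0) || any(recruitment_rate < 0))
    stop("inputs must be non-negative", call. = FALSE)
  dnap_free * recruitment_rate
}

#' Kolmogorov-Smirnov decision against a reference
#'
#' One-sample (against a cdf function) or two-sample (against reference
#' draws) KS test at level `alpha`, reported as an oracle record.  Used for
#' waiting-time exponentiality and cross-solver equivalence.
#'
#' @param samples Numeric vector (>= 100 values).
#' @param reference A cumulative distribution function, or a numeric vector
#'   of reference samples.
#' @param alpha Test level.
#' @param statistic Label for the report row.
#' @return One-row data frame: statistic, observed (KS distance), expected
#'   (0), p_value, alpha, pass.
#' @export
distributional_test <- function(samples, reference, alpha = 0.01,
                                statistic = "ks") {
  if (length(samples) < 100)
    stop("need at least 100 samples for a distributional test", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(samples, reference))
  data.frame(statistic = statistic,
             observed = unname(kt$statistic), expected = 0,
             p_value = kt$p.value, alpha = alpha,
             pass = kt$p.value > alpha,
             stringsAsFactors = FALSE)
}

oracle_row <- function(statistic, observed, expected, tolerance) {
  data.frame(statistic = statistic, observed = observed, expected = expected,
             p_value = NA_real_, alpha = tolerance,
             pass = abs(observed - expected) <= tolerance,
             stringsAsFactors = FALSE)
}

#' Run a validation suite and report oracle results
#'
#' Exercises the engine against independent references: closed-form
#' cascade/recruitment arithmetic, exponential waiting times, selection
#' frequencies of the three strategies, cross-solver equivalence on the
#' reversible isomerization, and the harmonic elongation-speed law.
#' Statistical decisions are taken at `alpha = 0.01` with a Bonferroni
#' correction over the tests of the suite.
#'
#' @param suite `"solver"`, `"engine"` or `"builders"`.
#' @param seed Integer seed for all simulated checks.
#' @param path Optional TSV output path for the report.
#' @return Data frame of oracle records (one per check).
#' @export
run_validation <- function(suite = c("solver", "engine", "builders"), seed = 1,
                           path = NULL) {
  suite <- match.arg(suite)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  if (suite == "solver") {
    alpha <- 0.01 / 5
    u <- with_seed(seed, stats::runif(1e4))
    tau <- waiting_time_sample(3, u)
    add(distributional_test(tau, function(q) stats::pexp(q, 3), alpha,
                            "waiting_time_exponential"))
    ent <- c(1, 2, 3)
    for (s in c("direct", "tree", "cr")) {
      sel <- sample_selections(ent, 1e5, seed, s)
      f <- tabulate(sel, 3) / 1e5
      add(oracle_row(paste0("selection_freq_max_err_", s),
                     max(abs(f - ent / sum(ent))), 0, 0.01))
    }
  } else if (suite == "engine") {
    m <- build_n_cascade(20, total_events = 2e4)
    tr <- run_simulation(m, t_end = 1e5, seed = seed, solver = "tree")
    add(oracle_row("cascade_event_count", event_count(tr), 2e4, 0))
    add(oracle_row("cascade_mass_conservation",
                   sum(utils::tail(as.data.frame(tr), 1)[, c("A0", "A20")]),
                   1e3, 0))
    sp <- build_single_polymerase(10000, 1000, 500, 50, seed = seed)
    trs <- run_simulation(sp, t_end = 400, seed = seed, solver = "cr",
                          log_period = 50)
    # the release is the final firing: t_final is the completion time
    speed <- 9999 / attr(trs, "t_final")
    add(oracle_row("elongation_speed", speed,
                   elongation_speed_oracle(c(50, 500, 1000)),
                   0.02 * elongation_speed_oracle(c(50, 500, 1000))))
  } else {
    add(oracle_row("mM_to_molecules", concentration_to_molecules(1), 6e5, 0))
    add(oracle_row("recruitment_balance", recruitment_balance(7.5, 0.1), 0.75, 1e-12))
    add(oracle_row("okazaki_interval", okazaki_recruitment_interval(1000, 750),
                   4 / 3, 1e-2))
    ck <- build_okazaki_clock(0.75)
    tr <- run_simulation(ck, t_end = 1e6, seed = seed, solver = "direct",
                         max_events = 1e4, log_period = 1e6)
    mean_int <- attr(tr, "t_final") / 1e4
    add(oracle_row("okazaki_interval_simulated", mean_int, 4 / 3,
                   3 * (4 / 3) / sqrt(1e4)))
  }
  report <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  report
}
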