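# Exact SSA loop and the three reaction-selection structures.

test_that("direct selection returns the first index whose cumulative sum reaches u*total", {
  expect_equal(select_direct(c(1, 2, 3), 0.5), 2)   # threshold 3.0, sums 1,3,6
  expect_equal(select_direct(c(0, 0, 7), 0.1), 3)
  expect_equal(select_direct(c(0, 0, 7), 0.9), 3)
  expect_equal(select_direct(5, 0.999), 1)
  expect_true(is.na(select_direct(c(0, 0, 0), 0.5)))
})

test_that("tree selection is index-identical to the direct method", {
  expect_equal(select_tree(c(1, 1, 1, 1), 0.6), 3)  # threshold 2.4
  set.seed(101)
  for (i in 1:1000) {
    a <- stats::runif(sample(1:40, 1), 0, 10)
    a[sample(length(a), length(a) %/% 3)] <- 0
    if (all(a == 0)) a[1] <- 1
    u <- stats::runif(1)
    expect_identical(select_tree(a, u), select_direct(a, u))
  }
})

test_that("composition-rejection groups channels by binary exponent", {
  expect_equal(cr_group_exponent(5), 2)     # 5 in [4, 8)
  expect_equal(cr_group_exponent(0.6), -1)  # 0.6 in [0.5, 1)
  expect_equal(cr_group_exponent(8), 3)
  expect_error(cr_group_exponent(0), "positive")
})

test_that("all three strategies select channels with probability a_j / total", {
  expected <- c(1, 2, 3) / 6
  for (s in c("direct", "tree", "cr")) {
    sel <- sample_selections(c(1, 2, 3), 1e5, seed = 42, strategy = s)
    freq <- tabulate(sel, 3) / 1e5
    expect_true(all(abs(freq - expected) < 0.01), info = s)
  }
})

test_that("waiting times follow the exponential inversion formula", {
  expect_equal(waiting_time_sample(1, exp(-1)), 1.0)
  expect_equal(waiting_time_sample(2, exp(-1)), 0.5)
  expect_error(waiting_time_sample(0, 0.5), "positive")
  set.seed(7)
  tau <- waiting_time_sample(3, stats::runif(1e5))
  expect_gt(quiet_ks(tau, stats::pexp, 3)$p.value, 0.01)
})

test_that("deterministic event counts: closed conversions fire a fixed number of times", {
  # single A -> B with 5 molecules: exactly 5 firings
  m <- ps_model()
  m <- add_free_chemical(m, "A", count = 5)
  m <- add_free_chemical(m, "B")
  m <- add_reaction(m, "r", "A", "B", k_forward = 1)
  for (s in c("direct", "tree", "cr")) {
    tr <- run_simulation(m, t_end = 1e6, seed = 1, solver = s, log_period = 1e6)
    expect_equal(event_count(tr), 5, info = s)
    expect_equal(final_row(tr)$B, 5, info = s)
  }
})

test_that("events interleave exactly with the reaction clock", {
  # no reactions can fire, one event at t = 10, t_end = 20
  m <- ps_model()
  m <- add_free_chemical(m, "A", count = 0)
  m <- add_free_chemical(m, "B")
  m <- add_reaction(m, "r", "A", "B", k_forward = 1)
  m <- add_event(m, 10, "ADD", "A", 7)
  m <- add_observable(m, c("A", "B"))
  tr <- run_simulation(m, t_end = 20, seed = 2, solver = "direct", log_period = 1)
  df <- as.data.frame(tr)
  # the event was applied and the revived channel then fired 7 times
  expect_equal(df$A[df$time == 10], 7)
  expect_equal(final_row(tr)$B, 7)
  expect_equal(event_count(tr), 7)
  # nothing happened before the event
  expect_true(all(df$A[df$time < 10] == 0))

  # an event beyond t_end is never applied
  m2 <- add_event(ps_model() |> add_free_chemical("X", 1) |>
                    add_reaction("rx", "X", "X", k_forward = 0) |> add_observable("X"),
                  50, "ADD", "X", 5)
  tr2 <- run_simulation(m2, t_end = 20, seed = 1, log_period = 5)
  expect_equal(final_row(tr2)$X, 1)
  expect_equal(event_count(tr2), 0)
})

test_that("identical model, seed and solver reproduce the trajectory bit for bit", {
  g <- test_genome(3)
  m <- build_gene_expression(g, granularity = "detailed")
  for (s in c("direct", "tree", "cr")) {
    t1 <- run_simulation(m, t_end = 15, seed = 9, solver = s, log_period = 1)
    t2 <- run_simulation(m, t_end = 15, seed = 9, solver = s, log_period = 1)
    expect_identical(as.data.frame(t1), as.data.frame(t2), info = s)
  }
  ta <- run_simulation(m, t_end = 15, seed = 9, solver = "cr", log_period = 1)
  tb <- run_simulation(m, t_end = 15, seed = 10, solver = "cr", log_period = 1)
  expect_false(identical(as.data.frame(ta), as.data.frame(tb)))
})

test_that("trajectory times are strictly increasing and cover [0, t_end]", {
  m <- build_isomerization(50)
  tr <- run_simulation(m, t_end = 12.5, seed = 4, log_period = 3)
  expect_equal(tr$time, c(0, 3, 6, 9, 12, 12.5))
  expect_true(all(diff(tr$time) > 0))
  # conservation at every log point
  expect_true(all(tr$A + tr$B == 50))
})

test_that("the dependency graph refreshes exactly the channels a firing touches", {
  # audited run: every 500 firings, all stored propensities are compared
  # against a from-scratch recomputation of every channel
  g <- test_genome(3)
  m <- build_gene_expression(g, granularity = "hybrid",
                             hybrid_detailed_fraction = 0.5, seed = 2)
  for (s in c("direct", "tree", "cr")) {
    tr <- run_simulation(m, t_end = 50, seed = 21, solver = s, log_period = 50,
                         max_events = 5000, check_every = 500)
    expect_equal(event_count(tr), 5000, info = s)
  }
})

test_that("terminal distributions agree across strategies and with the binomial law", {
  m <- build_isomerization(100, 1, 1)
  reps <- 600
  term <- function(solver, base) vapply(seq_len(reps), function(r) {
    final_row(run_simulation(m, t_end = 50, seed = base + r, solver = solver,
                             log_period = 50))$B
  }, numeric(1))
  bd <- term("direct", 50000)
  bt <- term("tree", 60000)
  bc <- term("cr", 70000)
  expect_gt(quiet_ks(bd, bt)$p.value, 0.01)
  expect_gt(quiet_ks(bd, bc)$p.value, 0.01)
  expect_gt(quiet_ks(bt, bc)$p.value, 0.01)
  # against Binomial(100, 1/2): mean within 3 SE
  expect_lt(abs(mean(c(bd, bt, bc)) - 50), 3 * 5 / sqrt(3 * reps))
})
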