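# The six reaction classes: propensity formulas and firing semantics.

test_that("chemical-reaction propensities use falling-factorial combinatorics", {
  m <- ps_model()
  m <- add_free_chemical(m, "A", count = 3)
  m <- add_free_chemical(m, "B", count = 4)
  m <- add_free_chemical(m, "C")
  m <- add_reaction(m, "r1", c(A = 1, B = 1), "C", k_forward = 2)
  m <- add_reaction(m, "r2", c(A = 2), "C", k_forward = 1)
  sys <- compile_system(m)
  expect_equal(propensity(sys, "r1")$forward, 2 * 3 * 4)
  # A + A with 5 molecules: ordered reactant pairs 5*4
  set_chemical_count(sys, "A", 5)
  expect_equal(propensity(sys, "r2")$forward, 5 * 4)
  # exhausted reactant
  set_chemical_count(sys, "B", 0)
  expect_equal(propensity(sys, "r1")$forward, 0)
  set_chemical_count(sys, "A", 1)
  expect_equal(propensity(sys, "r2")$forward, 0)
})

test_that("binding propensities track free counts, availability and origin units", {
  # free = 10, one available site with k_on = 0.1 -> 1.0
  sys <- compile_system(toy_binding_model(copies = 1, k_on = 0.1, k_off = 0.5))
  expect_equal(propensity(sys, "bind")$forward, 1.0)
  # fully occupied -> 0
  fire_reaction(sys, "bind")
  expect_equal(propensity(sys, "bind")$forward, 0)
  # reverse propensity sums k_off over units still on their origin site
  sys2 <- compile_system(toy_binding_model(copies = 2, k_on = 0.1, k_off = 0.5))
  fire_reaction(sys2, "bind")
  fire_reaction(sys2, "bind")
  expect_equal(propensity(sys2, "bind")$reverse, 1.0)
})

test_that("loading propensity decomposes by motif and respects exhaustion", {
  m <- toy_transcription_model(letters = "TTTTTACGTACGTACGTACG", copies = 2, ntp = 100)
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  fire_reaction(sys, "bind")
  # 2 units reading "T", ATP = 100, rate 0.1 -> contribution 20
  p <- propensity(sys, "load")
  expect_equal(unname(p$per_motif["T"]), 20)
  expect_equal(p$total, 20)
  # loaded chemical exhausted -> contribution 0
  set_chemical_count(sys, "ATP", 0)
  expect_equal(unname(propensity(sys, "load")$per_motif["T"]), 0)
})

test_that("a unit whose reading window overruns the end contributes nothing", {
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = 5)
  m <- add_free_chemical(m, "X", count = 100)
  m <- add_sequence(m, "s", "ACGTT", copies = 1)
  m <- add_bound_chemical(m, "B")
  m <- add_bound_chemical(m, "B2")
  # bound unit starts at position 3: a 3-letter window [3,6) overruns length 5
  m <- add_binding_site(m, "fam", "s", 0, 3, k_on = 1, reading_offset = 3)
  m <- add_sequence_binding(m, "bind", "F", "B", "fam")
  m <- add_loading(m, "load", "B",
                   data.frame(motif = c("TTA", "GTT"), loaded = "X", rate = 1,
                              post = "B2"))
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  expect_equal(propensity(sys, "load")$total, 0)
  check_consistency(sys)
})

test_that("firing a binding updates pools, occupancy and particles", {
  m <- toy_binding_model(copies = 3, free_count = 10)
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  expect_equal(chemical_count(sys, "F"), 9)
  expect_equal(chemical_count(sys, "Bnd"), 1)
  expect_equal(available_site_count(sys, "fam"), 2)
  u <- bound_members(sys, "Bnd")
  expect_equal(u$position, 0)
  expect_true(u$on_origin_site)

  # buffered free form: count unchanged, unit still created
  sysb <- compile_system(toy_binding_model(copies = 3, buffered = TRUE))
  fire_reaction(sysb, "bind")
  expect_equal(chemical_count(sysb, "F"), 10)
  expect_equal(chemical_count(sysb, "Bnd"), 1)
})

test_that("site choice is proportional to k_on x availability", {
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = 1, buffered = TRUE)
  m <- add_sequence(m, "s1", strrep("A", 20), copies = 1e5)
  m <- add_sequence(m, "s2", strrep("A", 20), copies = 1e5)
  m <- add_bound_chemical(m, "B")
  m <- add_binding_site(m, "fam", "s1", 0, 5, k_on = 0.1)
  m <- add_binding_site(m, "fam", "s2", 0, 5, k_on = 0.3)
  m <- add_sequence_binding(m, "bind", "F", "B", "fam")
  sys <- compile_system(m, seed = 11)
  for (i in 1:2000) fire_reaction(sys, "bind")
  frac <- table(bound_members(sys, "B")$sequence) / 2000
  expect_lt(abs(frac[["s1"]] - 0.25), 0.03)
  expect_lt(abs(frac[["s2"]] - 0.75), 0.03)
})

test_that("translocation moves by its step, releases the origin and obeys switches", {
  m <- toy_transcription_model(copies = 1)
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  fire_reaction(sys, "load", motif = "T")
  fire_reaction(sys, "polymerize")
  expect_equal(available_site_count(sys, "prom"), 0)  # still on origin
  fire_reaction(sys, "step")
  u <- bound_members(sys, "P_loading")
  expect_equal(u$position, 1)
  expect_false(u$on_origin_site)
  expect_equal(available_site_count(sys, "prom"), 1)  # origin released

  # codon stepping: step 3 from 0 lands at 3
  m3 <- ps_model()
  m3 <- add_free_chemical(m3, "F", count = 1)
  m3 <- add_sequence(m3, "s", strrep("ACGT", 5), copies = 1)
  m3 <- add_bound_chemical(m3, "B")
  m3 <- add_bound_chemical(m3, "B2")
  m3 <- add_binding_site(m3, "fam", "s", 0, 4, k_on = 1, reading_offset = 0)
  m3 <- add_sequence_binding(m3, "bind", "F", "B", "fam")
  m3 <- add_translocation(m3, "hop", "B", "B", step = 3, rate = 1)
  sys3 <- compile_system(m3)
  fire_reaction(sys3, "bind")
  fire_reaction(sys3, "hop")
  expect_equal(bound_members(sys3, "B")$position, 3)

  # a polymerase landing on an annotated terminator switches to termination
  sys4 <- compile_system(toy_transcription_model(letters = "TACG", copies = 1))
  fire_reaction(sys4, "bind")
  for (motif in c("T", "A", "C")) {
    fire_reaction(sys4, "load", motif = motif)
    fire_reaction(sys4, "polymerize")
    fire_reaction(sys4, "step")
  }
  # third step lands on position 3 = annotated terminator
  expect_equal(chemical_count(sys4, "P_term"), 1)
  expect_equal(chemical_count(sys4, "P_loading"), 0)
})

test_that("loading consumes the monomer carrier and emits byproducts", {
  sys <- compile_system(toy_transcription_model(ntp = 100))
  fire_reaction(sys, "bind")
  fire_reaction(sys, "load", motif = "T")   # reading T loads ATP
  expect_equal(chemical_count(sys, "ATP"), 99)
  expect_equal(chemical_count(sys, "PPi"), 1)
  expect_equal(chemical_count(sys, "P_loaded"), 1)
  expect_equal(chemical_count(sys, "P_loading"), 0)

  # buffered carrier kept constant to compensate consumption
  sysb <- compile_system(toy_transcription_model(ntp = 100, buffered_ntp = TRUE))
  fire_reaction(sysb, "bind")
  fire_reaction(sysb, "load", motif = "T")
  expect_equal(chemical_count(sysb, "ATP"), 100)
})

test_that("release looks the product up by origin family and position", {
  letters <- "TTTTTACGTACGTACGTACG"
  sys <- compile_system(toy_transcription_model(letters = letters))
  fire_reaction(sys, "bind")
  # drive the polymerase to the terminator
  for (i in seq_len(nchar(letters) - 1L)) {
    motif <- read_motif(letters, i - 1L, 1)
    fire_reaction(sys, "load", motif = motif)
    fire_reaction(sys, "polymerize")
    fire_reaction(sys, "step")
  }
  expect_equal(chemical_count(sys, "P_term"), 1)
  fire_reaction(sys, "terminate")
  expect_equal(chemical_count(sys, "rna"), 1)   # product copies incremented
  expect_equal(chemical_count(sys, "RNAP"), 3)  # polymerase recycled to the pool
  expect_equal(system_stats(sys)$live, 0)
  check_consistency(sys)
})

test_that("a release with no matching product interval is an error by default", {
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = 1)
  m <- add_sequence(m, "s", strrep("A", 30), copies = 1)
  m <- add_sequence(m, "prod", "AAA")
  m <- add_bound_chemical(m, "B")
  m <- add_binding_site(m, "fam", "s", 0, 5, k_on = 1, reading_offset = 20)
  m <- add_sequence_binding(m, "bind", "F", "B", "fam")
  m <- add_release(m, "rel", "B", rate = 1,
                   products = data.frame(family = "fam", first = 0, last = 5,
                                         product = "prod"))
  sys <- compile_system(m)
  fire_reaction(sys, "bind")   # unit sits at position 20, outside [0, 5)
  expect_error(fire_reaction(sys, "rel"), "matches no product interval")

  m2 <- ps_model()
  m2 <- add_free_chemical(m2, "F", count = 1)
  m2 <- add_sequence(m2, "s", strrep("A", 30), copies = 1)
  m2 <- add_sequence(m2, "prod", "AAA")
  m2 <- add_bound_chemical(m2, "B")
  m2 <- add_binding_site(m2, "fam", "s", 0, 5, k_on = 1, reading_offset = 20)
  m2 <- add_sequence_binding(m2, "bind", "F", "B", "fam")
  m2 <- add_release(m2, "rel", "B", rate = 1, on_unmatched = "warn",
                    products = data.frame(family = "fam", first = 0, last = 5,
                                          product = "prod"))
  sys2 <- compile_system(m2)
  fire_reaction(sys2, "bind")
  expect_warning(fire_reaction(sys2, "rel"), "matches no product interval")
  expect_equal(chemical_count(sys2, "prod"), 0)
})

test_that("timed-event actions add, set and clamp free pools", {
  m <- ps_model()
  m <- add_free_chemical(m, "tet", count = 0)
  m <- add_free_chemical(m, "tyr", count = 500)
  m <- add_reaction(m, "dummy", "tyr", "tet", k_forward = 0)
  sys <- compile_system(m)
  apply_event(sys, "ADD", "tet", 20000)
  expect_equal(chemical_count(sys, "tet"), 20000)
  apply_event(sys, "SET", "tyr", 0)
  expect_equal(chemical_count(sys, "tyr"), 0)
  # removal clamps at zero
  apply_event(sys, "SET", "tet", 5)
  apply_event(sys, "REMOVE_FREE", "tet", 10)
  expect_equal(chemical_count(sys, "tet"), 0)
})

test_that("wash-out events touch only the free pool, not sequestered complexes", {
  m <- toy_binding_model(copies = 2, free_count = 5)
  m <- add_free_chemical(m, "tet", count = 0)
  m <- add_bound_chemical(m, "Bnd_tet")
  m <- add_reaction(m, "sequester", c(tet = 1, Bnd = 1), c(Bnd_tet = 1),
                    k_forward = 1, k_backward = 0.1)
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  apply_event(sys, "ADD", "tet", 3)
  fire_reaction(sys, "sequester")
  expect_equal(chemical_count(sys, "Bnd_tet"), 1)
  expect_equal(chemical_count(sys, "tet"), 2)
  apply_event(sys, "REMOVE_FREE", "tet", 100)
  expect_equal(chemical_count(sys, "tet"), 0)
  expect_equal(chemical_count(sys, "Bnd_tet"), 1)  # bound form remains
  # the sequestered unit kept its location and position
  expect_equal(bound_members(sys, "Bnd_tet")$sequence, "tmpl")
  # reverse direction frees the unit and returns tetracycline
  fire_reaction(sys, "sequester", direction = "reverse")
  expect_equal(chemical_count(sys, "Bnd"), 1)
  expect_equal(chemical_count(sys, "tet"), 1)
})

test_that("mass is conserved in closed conversion networks", {
  m <- build_n_cascade(20, total_events = 2e4)
  tr <- run_simulation(m, t_end = 1e6, seed = 3, solver = "tree", log_period = 1)
  df <- as.data.frame(tr)
  expect_true(all(df$A0 + df$A20 <= 1000))      # intermediates in between
  expect_equal(utils::tail(df$A20, 1), 1000)    # all mass ends in the sink
  expect_equal(event_count(tr), 2e4)
})

test_that("a reversible isomerization equilibrates to the rate-constant ratio", {
  m <- build_isomerization(100, k_forward = 2, k_backward = 1)
  b <- vapply(1:300, function(r) {
    final_row(run_simulation(m, t_end = 30, seed = 400 + r, solver = "cr",
                             log_period = 30))$B
  }, numeric(1))
  # stationary law: B ~ Binomial(100, kf/(kf+kb) = 2/3)
  se <- sqrt(100 * (2 / 3) * (1 / 3) / 300)
  expect_lt(abs(mean(b) - 200 / 3), 3 * se)
})
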