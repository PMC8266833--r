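# Domain types: sites, availability, particles, filters.

test_that("binding-site registration validates bounds and counts availability", {
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = 1)
  m <- add_sequence(m, "s", strrep("A", 100), copies = 1)
  m <- add_bound_chemical(m, "B")
  m1 <- add_binding_site(m, "fam", "s", 0, 10, k_on = 1)
  m1 <- add_sequence_binding(m1, "bind", "F", "B", "fam")
  sys <- compile_system(m1)
  expect_equal(available_site_count(sys, "fam"), 1)

  # additivity over sites of one family
  m2 <- add_binding_site(m1, "fam", "s", 50, 60, k_on = 1)
  expect_equal(available_site_count(compile_system(m2), "fam"), 2)

  # out-of-bounds interval rejected
  m3 <- add_binding_site(m, "fam", "s", 95, 105, k_on = 1)
  expect_error(compile_system(m3), "out of bounds")

  # unknown sequence rejected
  m4 <- add_binding_site(m, "fam", "nope", 0, 10, k_on = 1)
  expect_error(compile_system(m4), "not a sequence|unknown species")

  expect_error(available_site_count(sys, "ghost"), "unknown site family")
})

test_that("occupancy is released by unbinding and counted per family", {
  # 1 site, copies = 3, one bound unit -> 2 available
  sys <- compile_system(toy_binding_model(copies = 3, k_off = 0.5))
  fire_reaction(sys, "bind")
  expect_equal(available_site_count(sys, "fam"), 2)
  expect_equal(chemical_count(sys, "Bnd"), 1)

  # both sites occupied -> 0; unbinding one -> 1
  m <- toy_binding_model(copies = 1, k_off = 0.5)
  m <- add_sequence(m, "tmpl2", strrep("ACGT", 25), copies = 1)
  m <- add_binding_site(m, "fam", "tmpl2", 0, 10, k_on = 0.1, k_off = 0.5,
                        reading_offset = 0)
  sys <- compile_system(m)
  fire_reaction(sys, "bind")
  fire_reaction(sys, "bind")
  expect_equal(available_site_count(sys, "fam"), 0)
  expect_equal(propensity(sys, "bind")$forward, 0)
  fire_reaction(sys, "bind", direction = "reverse")
  expect_equal(available_site_count(sys, "fam"), 1)
  check_consistency(sys)
})

test_that("read_motif returns windows inside the sequence and NA on overrun", {
  expect_equal(read_motif("ATGC", 0, 3), "ATG")
  expect_identical(read_motif("ATGC", 3, 3), NA_character_)
  expect_equal(read_motif("T", 0, 1), "T")
  expect_error(read_motif("ATGC", -1, 2), "non-negative")
})

test_that("reassignment moves particles between classes and updates filters", {
  m <- toy_transcription_model(copies = 3)
  sys <- compile_system(m)
  for (i in 1:3) fire_reaction(sys, "bind")
  expect_equal(chemical_count(sys, "P_loading"), 3)
  expect_equal(chemical_count(sys, "P_loaded"), 0)

  reassign_unit(sys, "P_loading", "P_loaded", member = 1)
  expect_equal(chemical_count(sys, "P_loading"), 2)
  expect_equal(chemical_count(sys, "P_loaded"), 1)
  # total particle count unchanged
  expect_equal(system_stats(sys)$live, 3)

  # the loading reaction sees one fewer particle reading 'T' (P_loaded has no
  # template filter): recomputed decomposition drops accordingly
  expect_equal(unname(propensity(sys, "load")$per_motif["T"]), 0.1 * 100 * 2)

  # involution: A -> B -> A restores counts
  reassign_unit(sys, "P_loaded", "P_loading", member = 1)
  expect_equal(chemical_count(sys, "P_loading"), 3)
  expect_equal(unname(propensity(sys, "load")$per_motif["T"]), 0.1 * 100 * 3)
  check_consistency(sys)

  expect_error(reassign_unit(sys, "P_loaded", "P_loading", member = 1),
               "no members")
})

test_that("sample_member draws uniformly and errors on an empty class", {
  # four units on four distinct sequences of one family
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = 10)
  m <- add_bound_chemical(m, "B")
  for (i in 1:4) {
    s <- paste0("s", i)
    m <- add_sequence(m, s, strrep("ACGT", 10), copies = 1)
    m <- add_binding_site(m, "fam", s, 0, 4, k_on = 1, reading_offset = 0)
  }
  m <- add_sequence_binding(m, "bind", "F", "B", "fam")
  sys <- compile_system(m, seed = 5)
  for (i in 1:4) fire_reaction(sys, "bind")

  draws <- vapply(1:40000, function(i) sample_member(sys, "B")$sequence, character(1))
  freq <- table(factor(draws, levels = paste0("s", 1:4))) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))
  expect_gt(stats::chisq.test(table(draws))$p.value, 1e-3)

  # single member drawn with probability one
  sys1 <- compile_system(toy_binding_model())
  fire_reaction(sys1, "bind")
  expect_equal(sample_member(sys1, "Bnd")$sequence, "tmpl")
  # empty class signals an impossible reaction
  m0 <- add_bound_chemical(toy_binding_model(), "Empty")
  expect_error(sample_member(compile_system(m0), "Empty"), "no members")
})

test_that("particle bookkeeping stays consistent under random firing", {
  g <- test_genome(4)
  m <- build_gene_expression(g, granularity = "detailed")
  sys <- compile_system(m)
  tr <- run_simulation(sys, t_end = 1e4, seed = 17, solver = "cr",
                       log_period = 1e4, max_events = 20000)
  expect_equal(event_count(tr), 20000)
  st <- system_stats(sys)
  expect_equal(st$live, st$created - st$destroyed)
  check_consistency(sys)  # occupancy, family/template filters vs scratch
})

test_that("sequences are immutable after registration and copies gate binding", {
  sys <- compile_system(toy_binding_model(copies = 0))
  expect_equal(available_site_count(sys, "fam"), 0)
  expect_equal(propensity(sys, "bind")$forward, 0)
  set_chemical_count(sys, "tmpl", 4)
  expect_equal(available_site_count(sys, "fam"), 4)
  expect_equal(propensity(sys, "bind")$forward, 10 * 0.1 * 4)
})
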