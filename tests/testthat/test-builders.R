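# Benchmark and case-study model builders.

test_that("n-cascade initial counts follow total_events / n", {
  m10 <- build_n_cascade(10)
  expect_equal(m10$records[[1]]$count, 100000)
  m1000 <- build_n_cascade(1000)
  expect_equal(m1000$records[[1]]$count, 1000)
  expect_error(build_n_cascade(7), "does not divide")
})

test_that("synthetic genomes are deterministic and well-formed", {
  g1 <- synthesize_genome(6, c(300, 500), seed = 9)
  g2 <- synthesize_genome(6, c(300, 500), seed = 9)
  expect_identical(g1, g2)
  g3 <- synthesize_genome(6, c(300, 500), seed = 10)
  expect_false(identical(g1$letters, g3$letters))
  # constructive invariants (validate_genome runs inside the generator; run
  # the checks here against the public fields)
  gg <- g1$genes
  expect_true(all(gg$promoter_first < gg$tss & gg$tss < gg$terminator))
  expect_true(all((gg$stop_codon - gg$start_codon) %% 3 == 0))
  expect_true(all(gg$terminator < nchar(g1$letters)))
  # coding bodies are free of internal stop codons
  for (i in seq_len(nrow(gg))) {
    tx <- substr(g1$letters, gg$tss[i] + 1, gg$tss[i] + gg$mrna_len[i])
    body <- substr(tx, gg$start_codon[i] + 1, gg$stop_codon[i])
    cods <- substring(body, seq(1, nchar(body), 3), seq(3, nchar(body), 3))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(synthesize_genome(3, c(20, 40)), "degenerate")
})

test_that("a small genome builds and runs under all three granularities", {
  g <- test_genome(4, seed = 8)
  for (gr in c("detailed", "aggregated", "hybrid")) {
    m <- build_gene_expression(g, granularity = gr,
                               hybrid_detailed_fraction = 0.5, seed = 3)
    tr <- run_simulation(m, t_end = 30, seed = 5, solver = "cr", log_period = 10)
    expect_gt(event_count(tr), 0)
    expect_true(all(is.finite(as.matrix(as.data.frame(tr)))))
  }
})

test_that("metabolite renewal modes regenerate consumed nucleotides", {
  g <- test_genome(3, seed = 21)
  # detailed renewal: NTPs are consumed and regenerated one by one
  md <- build_gene_expression(g, granularity = "detailed", metabolism = "detailed")
  trd <- run_simulation(md, t_end = 40, seed = 2, solver = "cr", log_period = 10,
                        observables = c("ATP", "AMP", "protein_g01"))
  fin <- final_row(trd)
  expect_lt(fin$ATP, concentration_to_molecules(1))  # net consumption visible
  expect_gte(fin$AMP, 0)
  # stacked renewal: monophosphates recycled in stacks of 100, so the
  # standing pool stays bounded near the stack size
  ms <- build_gene_expression(g, granularity = "detailed", metabolism = "stacked")
  trs <- run_simulation(ms, t_end = 40, seed = 2, solver = "cr", log_period = 10,
                        observables = c("ATP", "AMP"))
  expect_lt(final_row(trs)$AMP, 1000)
  check_consistency(compile_system(ms))
})

test_that("aggregated mode adds two reactions per gene per process", {
  g <- synthesize_genome(20, c(300, 600), seed = 12)
  m <- build_gene_expression(g, granularity = "aggregated")
  nm <- vapply(m$records, function(r) if (is.null(r[["name"]])) "" else r[["name"]],
               character(1))
  # transcription: one +50 translocation and one release per gene
  expect_length(grep("^tx_agg_(move|rel)_", nm), 40)
  expect_length(grep("^tl_agg_(move|rel)_", nm), 40)
})

test_that("the aggregated hop lands the polymerase 50 bases past its site", {
  g <- test_genome(2, seed = 3)
  m <- build_gene_expression(g, granularity = "aggregated")
  sys <- compile_system(m)
  fire_reaction(sys, "bind_prom_g01")
  tss <- attr(m, "gene_info")$tss[1]
  expect_equal(bound_members(sys, "RNAPa_g01")$position, tss)
  fire_reaction(sys, "tx_agg_move_g01")
  expect_equal(bound_members(sys, "RNAPa2_g01")$position, tss + 50)
  # the binding site is free again for the next polymerase
  expect_equal(available_site_count(sys, "prom_g01"),
               g$genes$tu_count[1])
})

test_that("the hybrid split draws the documented fraction of detailed genes", {
  g <- synthesize_genome(20, c(300, 600), seed = 12)
  m <- build_gene_expression(g, granularity = "hybrid",
                             hybrid_detailed_fraction = 0.05, seed = 1)
  gi <- attr(m, "gene_info")
  expect_equal(sum(gi$detailed), 1)    # 95% of genes stay aggregated
  expect_equal(sum(!gi$detailed), 19)
  m2 <- build_gene_expression(g, granularity = "hybrid",
                              hybrid_detailed_fraction = 0.05, seed = 1)
  expect_identical(attr(m2, "gene_info"), gi)  # seeded split is reproducible
  expect_error(build_gene_expression(g, granularity = "hybrid",
                                     hybrid_detailed_fraction = 1.5),
               "\\[0, 1\\]")
})

test_that("the tetracycline overlay only appends records to the base model", {
  g <- test_genome(3)
  base <- build_gene_expression(g, granularity = "detailed")
  ext <- build_tetracycline_extension(base, 20000)
  n <- length(base$records)
  expect_identical(ext$records[seq_len(n)], base$records)
  kinds <- vapply(ext$records[-seq_len(n)], function(r) r$kind, character(1))
  expect_setequal(unique(kinds),
                  c("FreeChemical", "BoundChemical", "ChemicalReaction",
                    "Event", "Observe"))
  # injection + repeated purifications of the free pool only
  ev <- Filter(function(r) r$kind == "Event", ext$records)
  expect_equal(vapply(ev, `[[`, numeric(1), "time"), c(200, 400, 450, 500, 550))
  expect_equal(vapply(ev, `[[`, character(1), "event_kind"),
               c("ADD", rep("REMOVE_FREE", 4)))
  # an aggregated-only base has no 70S loading-phase class
  agg <- build_gene_expression(g, granularity = "aggregated")
  expect_error(build_tetracycline_extension(agg, 100), "R_loading")
})

test_that("the T-box overlay requires its gene in the detailed set", {
  g <- test_genome(5)
  agg <- build_gene_expression(g, granularity = "aggregated")
  expect_error(build_tbox_extension(agg, "g02"), "aggregated mode")
  hyb <- build_gene_expression(g, granularity = "hybrid",
                               hybrid_detailed_fraction = 0, detailed_genes = "g02")
  expect_true(attr(hyb, "gene_info")$detailed[2])
  m <- build_tbox_extension(hyb, "g02")
  expect_error(build_tbox_extension(hyb, "gX"), "unknown regulated gene")
  # depletion and re-injection events at 200 s and 600 s
  ev <- Filter(function(r) r$kind == "Event" && r$target == "aa_tyr", m$records)
  expect_equal(vapply(ev, `[[`, numeric(1), "time"), c(200, 600))
  expect_equal(vapply(ev, `[[`, numeric(1), "amount")[1], 0)
  # the abort path emits the annotated aborted transcript, not the mRNA
  rel <- Filter(function(r) r$kind == "Release" && r$name == "tbox_abort_release",
                m$records)[[1]]
  expect_equal(rel$product, "aborted_g02")
  expect_match(rel$releasing_class, "RNAP_abort")
})

test_that("concentrations convert at 6e5 molecules per mM in a 1e-15 L cell", {
  expect_equal(concentration_to_molecules(1), 6e5)
  expect_equal(concentration_to_molecules(0), 0)
  expect_equal(concentration_to_molecules(10), 6e6)
  expect_error(concentration_to_molecules(-1), "non-negative")
})

test_that("the replication fork couples detailed leading-strand synthesis with the recruitment clock", {
  m <- build_replication_fork(2000)
  sys <- compile_system(m)
  # recruitment channel propensity is exactly |DNAP_free| * r = 3/4
  expect_equal(propensity(sys, "okazaki_recruitment")$forward, 0.75)
  tr <- run_simulation(m, t_end = 20, seed = 6, solver = "cr", log_period = 5)
  fin <- final_row(tr)
  expect_gt(fin$nascent_strand, 0)      # leading strand completed passes
  expect_gt(fin$DNAP_engaged, 5)        # recruitments near 20 / 1.33
  expect_lt(fin$DNAP_engaged, 30)
})
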