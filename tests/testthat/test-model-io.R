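# Model dialect parsing, serialization round trips, trajectory output.

toy_dir <- function() system.file("extdata", "toy_transcription", package = "polysim")

test_that("the toy model directory parses, compiles and runs", {
  m <- parse_model(toy_dir())
  kinds <- vapply(m$records, function(r) r$kind, character(1))
  expect_setequal(unique(kinds),
                  c("FreeChemical", "BoundChemical", "Sequence", "BindingSite",
                    "SequenceBinding", "Loading", "ChemicalReaction",
                    "Translocation", "Switch", "SwitchSite", "Release", "Init",
                    "Observe"))
  tr <- run_simulation(m, t_end = 100, seed = 3, solver = "cr", log_period = 10)
  expect_gt(final_row(tr)$rna, 0)                 # transcripts were produced
  expect_true(final_row(tr)$RNAP %in% 0:3)        # pool conserved (some engaged)
  expect_gt(sum(tr$RNAP == 3), 0)                 # polymerases do get recycled
})

test_that("parse errors carry file name and line number", {
  d <- withr::local_tempdir()
  writeLines(c("FreeChemical A", "ChemicalReaction r 1 0 : 1 A -> 1 Ghost"),
             file.path(d, "bad.in"))
  expect_error(parse_model(d), "bad\\.in:2: .*undeclared.*'Ghost'")

  d2 <- withr::local_tempdir()
  writeLines(c("FreeChemical A", "FreeChemical A"), file.path(d2, "dup.in"))
  expect_error(parse_model(d2), "dup\\.in:2: duplicate declaration of 'A'")

  d3 <- withr::local_tempdir()
  writeLines("Sequence s ACGT", file.path(d3, "a.in"))
  writeLines("BindingSite f s 2 9 1 0 2", file.path(d3, "b.in"))
  expect_error(parse_model(d3), "b\\.in:1: site \\[2,9\\) out of bounds")

  d4 <- withr::local_tempdir()
  writeLines("Wibble x", file.path(d4, "a.in"))
  expect_error(parse_model(d4), "unknown record kind 'Wibble'")

  expect_error(parse_model(withr::local_tempdir()), "no \\.in files")
  expect_error(parse_model(file.path(tempdir(), "does-not-exist")),
               "no such model directory")
})

test_that("declarations may live in an earlier file of the directory", {
  d <- withr::local_tempdir()
  writeLines(c("FreeChemical A", "FreeChemical B"), file.path(d, "01_chems.in"))
  writeLines("ChemicalReaction r 2 0 : 1 A -> 1 B", file.path(d, "02_rxns.in"))
  writeLines("Init A 3", file.path(d, "03_init.in"))
  m <- parse_model(d)
  tr <- run_simulation(m, t_end = 100, seed = 1, log_period = 100)
  expect_equal(event_count(tr), 3)
  # extension by one extra file leaves existing records untouched
  writeLines(c("FreeChemical C", "Event 1 ADD C 10"), file.path(d, "04_more.in"))
  m2 <- parse_model(d)
  expect_identical(m$records, m2$records[seq_along(m$records)])
})

test_that("serialization round-trips structurally", {
  # a cascade round-trips to an identical system
  m <- build_n_cascade(10, total_events = 1000)
  d <- withr::local_tempdir()
  write_model(m, d)
  m2 <- parse_model(d)
  t1 <- run_simulation(m, t_end = 1e5, seed = 6, log_period = 1e5)
  t2 <- run_simulation(m2, t_end = 1e5, seed = 6, log_period = 1e5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # serialize(parse(serialize)) is a fixed point
  expect_identical(serialize_model(m2), {
    d2 <- withr::local_tempdir()
    write_model(m2, d2)
    serialize_model(parse_model(d2))
  })

  # names are declared before use in the emitted text
  txt <- serialize_model(m)
  first_decl <- min(grep("^FreeChemical", txt))
  first_use <- min(grep("^ChemicalReaction", txt))
  expect_lt(first_decl, first_use)

  # a generated gene-expression model (loading tables, releases, switches,
  # events) also parses back to an equivalent system
  g <- test_genome(3)
  base <- build_gene_expression(g, granularity = "hybrid",
                                hybrid_detailed_fraction = 0.5, seed = 4)
  mt <- build_tetracycline_extension(base, 1000, t_inject = 5, t_purify = 10)
  d3 <- withr::local_tempdir()
  write_model(mt, d3)
  mt2 <- parse_model(d3)
  ta <- run_simulation(mt, t_end = 20, seed = 8, log_period = 5)
  tb <- run_simulation(mt2, t_end = 20, seed = 8, log_period = 5,
                       observables = names(ta)[-1])
  strip <- function(x) as.data.frame(lapply(as.data.frame(x), as.numeric))
  expect_identical(strip(ta), strip(tb))
})

test_that("loading tables serialize one motif per line and reparse", {
  m <- parse_model(toy_dir())
  txt <- serialize_model(m)
  i <- grep("^Loading load P_loading$", txt)
  expect_length(i, 1)
  rows <- txt[(i + 1):(i + 4)]
  expect_true(all(grepl("^[ACGT] [ACGU]TP 0\\.001 P_loaded PPi$", rows)))
  expect_equal(txt[i + 5], "")  # blank line terminates the table
})

test_that("trajectories write and re-read exactly", {
  m <- build_isomerization(40)
  tr <- run_simulation(m, t_end = 5, seed = 2, log_period = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(names(back), c("time", "A", "B"))
  expect_equal(nrow(back), nrow(tr))
  expect_identical(back$A, as.integer(tr$A))   # integer counts round-trip
  expect_identical(back$B, as.integer(tr$B))

  # log period larger than t_end: exactly the initial and final rows
  tr2 <- run_simulation(m, t_end = 5, seed = 2, log_period = 100)
  expect_equal(tr2$time, c(0, 5))
})

test_that("run metadata sidecar is key-value text", {
  f <- withr::local_tempfile(fileext = ".meta")
  write_run_metadata(f, t_end = 10, seed = 3, solver = "cr", log_period = 1)
  kv <- read.delim(f, header = FALSE)
  expect_true(all(c("seed", "solver", "t_end") %in% kv$V1))
  expect_equal(kv$V2[kv$V1 == "solver"], "cr")
})
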