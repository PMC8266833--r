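# Shared fixtures, all built in code.

# Minimal two-site binding model: one free chemical binding to a family of
# sites on one or more sequences.
toy_binding_model <- function(copies = 1, k_on = 0.1, k_off = 0,
                              free_count = 10, buffered = FALSE) {
  m <- ps_model()
  m <- add_free_chemical(m, "F", count = free_count, buffered = buffered)
  m <- add_sequence(m, "tmpl", strrep("ACGT", 25), copies = copies)  # length 100
  m <- add_bound_chemical(m, "Bnd")
  m <- add_binding_site(m, "fam", "tmpl", 0, 10, k_on = k_on, k_off = k_off,
                        reading_offset = 0)
  m <- add_sequence_binding(m, "bind", "F", "Bnd", "fam")
  m
}

# Simplified one-polymerase transcription cycle on a short template with an
# annotated terminator, exercising binding, loading, a bound-to-bound
# chemical step, translocation, switching and release.
toy_transcription_model <- function(letters = "TTTTTACGTACGTACGTACG",
                                    copies = 1, ntp = 100, buffered_ntp = FALSE) {
  m <- ps_model()
  m <- add_free_chemical(m, "RNAP", count = 3)
  m <- add_free_chemical(m, "ATP", count = ntp, buffered = buffered_ntp)
  m <- add_free_chemical(m, "UTP", count = ntp, buffered = buffered_ntp)
  m <- add_free_chemical(m, "GTP", count = ntp, buffered = buffered_ntp)
  m <- add_free_chemical(m, "CTP", count = ntp, buffered = buffered_ntp)
  m <- add_free_chemical(m, "PPi")
  m <- add_sequence(m, "dna", letters, copies = copies)
  m <- add_sequence(m, "rna", letters, copies = 0)
  for (cl in c("P_loading", "P_loaded", "P_ready", "P_term"))
    m <- add_bound_chemical(m, cl)
  m <- add_binding_site(m, "prom", "dna", 0, 4, k_on = 0.1, k_off = 0.5,
                        reading_offset = 0)
  m <- add_sequence_binding(m, "bind", "RNAP", "P_loading", "prom")
  m <- add_loading(m, "load", "P_loading",
                   data.frame(motif = c("T", "A", "C", "G"),
                              loaded = c("ATP", "UTP", "GTP", "CTP"),
                              rate = 0.1, post = "P_loaded", byproducts = "PPi"))
  m <- add_reaction(m, "polymerize", reactants = "P_loaded", products = "P_ready",
                    k_forward = 500)
  m <- add_translocation(m, "step", "P_ready", "P_loading", step = 1, rate = 50)
  m <- add_switch(m, "term_switch", "P_loading", "P_term")
  m <- add_switch_site(m, "dna", nchar(letters) - 1L, "term_switch")
  m <- add_release(m, "terminate", "P_term", rate = 1, freed = "RNAP",
                   products = data.frame(family = "prom",
                                         first = nchar(letters) - 1L,
                                         last = nchar(letters), product = "rna"))
  add_observable(m, c("RNAP", "rna", "PPi"))
}

test_genome <- function(n = 10, seed = 42) synthesize_genome(n, c(300, 600), seed = seed)

final_row <- function(tr) utils::tail(as.data.frame(tr), 1)

quiet_ks <- function(...) suppressWarnings(stats::ks.test(...))
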