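# Programmatic model builders for the benchmark and case-study systems.

#' Default kinetic parameters for the gene-expression models
#'
#' Rates follow the bacterial literature values used throughout the package:
#' elongation is modeled as a three-step cycle per position (loading of the
#' monomer carrier, polymerization, translocation) with the limiting step
#' set to the known global speed and the other steps 10-100x faster.
#'
#' * transcription: translocation 50 /s (limiting), polymerization 500 /s,
#'   effective loading 600-2100 /s depending on the NTP;
#' * translation: loading ~20 /s (limiting), transpeptidation 150 /s,
#'   translocation 150 /s (codon step of 3);
#' * replication: translocation 750 /s (limiting), polymerization 10,000 /s,
#'   effective loading 1000-10,000 /s depending on the dNTP; Okazaki
#'   fragments of 1000 bp give one new polymerase recruitment per 1.33 s,
#'   encoded by |DNAP_free| x r_recruitment = 3/4 with 10 DNAP copies;
#' * initiation and termination last about 1 s (release rate 1 /s);
#' * cell volume 1e-15 L, so 1 mM corresponds to 6e5 molecules.
#'
#' @return Nested list of parameters; override entries and pass the result
#'   to the builders.
#' @export
expression_params <- function() {
  list(
    transcription = list(
      translocation = 50, polymerization = 500,
      # effective loading rates (1/s) per NTP; rate constants are these
      # divided by the buffered NTP pool
      loading_eff = c(ATP = 2100, UTP = 1100, GTP = 1400, CTP = 600),
      k_on_promoter = 0.002, k_off_promoter = 0.02, termination = 1),
    translation = list(
      loading_eff = 20, transpeptidation = 150, translocation = 150,
      k_on_rbs = 0.01, k_off_rbs = 0.02, termination = 1),
    replication = list(
      translocation = 750, polymerization = 10000,
      loading_eff = c(dATP = 10000, dTTP = 8000, dGTP = 4000, dCTP = 1000),
      okazaki_length = 1000, dnap_copies = 10, recruitment_rate = 0.1),
    counts = list(
      rnap = 50, ribosome = 300, ntp = concentration_to_molecules(1),
      dntp = 1e8, trna_bulk = 80000, trna_bulk_uncharged = 2000,
      trna_tyr = 2000, trna_tyr_uncharged = 100, aa_tyr = 1e6, aa_bulk = 1e6),
    charging_k = 1e-6,
    volume = 1e-15)
}

#' Convert a concentration to a molecule count
#'
#' `round(conc_mM * 1e-3 * avogadro * volume)`: in the default 1e-15 L cell,
#' 1 mM corresponds to 6e5 molecules.
#'
#' @param conc_mM Concentration in mmol/L (non-negative).
#' @param volume_L Cell volume in liters.
#' @param avogadro Avogadro constant (the conventional rounded 6e23).
#' @return Molecule count.
#' @export
#' @examples
#' concentration_to_molecules(1)  # 600000
concentration_to_molecules <- function(conc_mM, volume_L = 1e-15, avogadro = 6e23) {
  if (any(conc_mM < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (volume_L <= 0 || avogadro <= 0) stop("volume and Avogadro constant must be positive",
                                           call. = FALSE)
  round(conc_mM * 1e-3 * avogadro * volume_L)
}

#' Build a linear conversion cascade
#'
#' An n-cascade has n+1 chemicals `A0 ... An` and n unimolecular conversions
#' `Ai -> Ai+1` at unit rate.  Starting with `total_events / n` molecules of
#' `A0`, the run performs exactly `total_events` firings before every
#' molecule reaches `An`, whatever the seed: each of the initial molecules
#' fires each of the n reactions exactly once.  This closed system is the
#' standard scaling benchmark for reaction-selection structures.
#'
#' @param n Number of reactions; must divide `total_events`.
#' @param total_events Total firings at completion (default 1,000,000).
#' @param rate Rate constant of every conversion.
#' @return A `polysim_model` observing `A0` and `An`.
#' @export
build_n_cascade <- function(n, total_events = 1e6, rate = 1) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (total_events %% n != 0)
    stop(sprintf("n = %d does not divide total_events = %s", n,
                 format(total_events, scientific = FALSE)), call. = FALSE)
  nm <- paste0("A", 0:n)
  recs <- vector("list", 2L * n + 3L)
  recs[[1]] <- list(kind = "FreeChemical", name = nm[1],
                    count = total_events / n, buffered = FALSE)
  for (i in seq_len(n)) {
    recs[[1L + i]] <- list(kind = "FreeChemical", name = nm[i + 1L],
                           count = 0, buffered = FALSE)
    recs[[1L + n + i]] <- list(
      kind = "ChemicalReaction", name = paste0("conv", i),
      reactants = stats::setNames(1, nm[i]), products = stats::setNames(1, nm[i + 1L]),
      k_forward = rate, k_backward = 0)
  }
  recs[[2L * n + 2L]] <- list(kind = "Observe", names = c(nm[1], nm[n + 1L]))
  recs[[2L * n + 3L]] <- NULL
  ps_model_from_records(recs[!vapply(recs, is.null, logical(1))])
}

#' Build a reversible two-state isomerization
#'
#' `A <-> B` with `n_molecules` starting in A.  At stationarity each
#' molecule is independently in B with probability `kf / (kf + kb)`, so the
#' count of B follows a binomial law -- the analytic reference for
#' cross-solver equivalence tests.
#'
#' @param n_molecules Initial count of A.
#' @param k_forward,k_backward Rate constants of the two directions.
#' @return A `polysim_model` observing A and B.
#' @export
build_isomerization <- function(n_molecules = 100, k_forward = 1, k_backward = 1) {
  m <- ps_model()
  m <- add_free_chemical(m, "A", count = n_molecules)
  m <- add_free_chemical(m, "B")
  m <- add_reaction(m, "iso", reactants = "A", products = "B",
                    k_forward = k_forward, k_backward = k_backward)
  add_observable(m, c("A", "B"))
}

#' Build a constant-rate recruitment clock
#'
#' A buffered polymerase pool firing a recruitment reaction at constant
#' total propensity, as on the lagging strand of a replication fork where
#' `|DNAP_free| x r_recruitment = 3/4` makes a new polymerase start an
#' Okazaki fragment every 1.33 s on average.
#'
#' @param recruitment_propensity Total propensity in 1/s (default 3/4).
#' @param dnap_copies Size of the buffered polymerase pool.
#' @return A `polysim_model` whose single reaction fires at the requested
#'   constant propensity; observe `DNAP_engaged` to count recruitments.
#' @export
build_okazaki_clock <- function(recruitment_propensity = 0.75, dnap_copies = 10) {
  stopifnot(recruitment_propensity > 0, dnap_copies >= 1)
  m <- ps_model()
  m <- add_free_chemical(m, "DNAP_free", count = dnap_copies, buffered = TRUE)
  m <- add_free_chemical(m, "DNAP_engaged")
  m <- add_reaction(m, "okazaki_recruitment", reactants = "DNAP_free",
                    products = "DNAP_engaged",
                    k_forward = recruitment_propensity / dnap_copies)
  add_observable(m, "DNAP_engaged")
}

#' Build a single-polymerase elongation raceway
#'
#' One polymerase runs once along a random template through the three-step
#' cycle loading -> polymerization -> translocation, and releases a product
#' at the end.  The time at which the product appears measures the realized
#' elongation speed, which the harmonic-cycle oracle
#' [elongation_speed_oracle()] predicts as `1 / sum(1/k_i)`.
#'
#' @param template_length Template length in nt.
#' @param loading_rate,polymerization_rate,translocation_rate Cycle rates (1/s).
#' @param seed Seed for the random template.
#' @return A `polysim_model` observing the product count `transcript`.
#' @export
build_single_polymerase <- function(template_length = 10000, loading_rate = 1000,
                                    polymerization_rate = 500,
                                    translocation_rate = 50, seed = 1) {
  stopifnot(template_length >= 10)
  letters <- with_seed(seed, random_letters(template_length))
  m <- ps_model()
  m <- add_free_chemical(m, "polymerase", count = 1)
  m <- add_free_chemical(m, "monomer", count = 1, buffered = TRUE)
  m <- add_sequence(m, "template", letters, copies = 1)
  m <- add_sequence(m, "transcript", letters, copies = 0)
  for (cl in c("P_loading", "P_loaded", "P_ready", "P_term"))
    m <- add_bound_chemical(m, cl)
  m <- add_binding_site(m, "start", "template", 0, 10, k_on = 1000, k_off = 0,
                        reading_offset = 0)
  m <- add_sequence_binding(m, "bind", "polymerase", "P_loading", "start")
  m <- add_loading(m, "load", "P_loading",
                   data.frame(motif = BASES, loaded = "monomer",
                              rate = loading_rate, post = "P_loaded"))
  m <- add_reaction(m, "polymerize", reactants = "P_loaded", products = "P_ready",
                    k_forward = polymerization_rate)
  m <- add_translocation(m, "step", "P_ready", "P_loading", step = 1,
                         rate = translocation_rate)
  m <- add_switch(m, "end_switch", "P_loading", "P_term")
  m <- add_switch_site(m, "template", template_length - 1L, "end_switch")
  m <- add_release(m, "finish", "P_term", rate = 1e6,
                   products = data.frame(family = "start", first = 0,
                                         last = template_length,
                                         product = "transcript"))
  add_observable(m, "transcript")
}

# ---------------------------------------------------------------------------
# Gene expression on a synthetic genome.

tx_cycle_speed <- function(params) {
  tx <- params$transcription
  1 / (1 / tx$translocation + 1 / tx$polymerization + 1 / mean(tx$loading_eff))
}

tl_cycle_speed <- function(params) {
  tl <- params$translation
  1 / (1 / mean(tl$loading_eff) + 1 / tl$transpeptidation + 1 / tl$translocation)
}

# complement pairing template base -> loaded NTP
NTP_FOR_BASE <- c(T = "ATP", A = "UTP", C = "GTP", G = "CTP")

#' Build a gene-expression model from a synthetic genome
#'
#' Constructs transcription and translation for every gene of a
#' [synthesize_genome()] genome at one of three granularities:
#'
#' * `"detailed"`: one generic reaction set shared by all genes --
#'   sequence binding of the polymerase at promoters, per-base loading of
#'   the complementary NTP, polymerization and translocation, switch-site
#'   termination and release of the transcript; likewise codon-per-codon
#'   translation with charged-tRNA loading, transpeptidation and a 3 nt
#'   translocation step.  Genes contribute only annotations (sites, switch
#'   sites, product-table rows) plus their transcript/protein species.
#' * `"aggregated"`: binding is still sequence-based, then the bound
#'   polymerase is translocated +50 bases from the binding site (freeing
#'   the site), the gene product is created in one step, and the
#'   polymerase is released -- exactly two reactions (one translocation,
#'   one release) per gene and per process beyond its binding.
#' * `"hybrid"`: detailed for a seeded random fraction of genes (default
#'   5%), aggregated for the rest.
#'
#' Promoters and ribosome binding sites all share the same strength.
#' Messengers and proteins are not degraded and accumulate.  NTP pools are
#' buffered by default (`metabolism = "constant"`); `"detailed"` regenerates
#' consumed nucleotides one by one through pseudo-metabolic reactions, and
#' `"stacked"` regenerates them in stacks of 100.
#'
#' @param genome A `ps_genome`.
#' @param params Parameter list from [expression_params()].
#' @param granularity `"detailed"`, `"aggregated"` or `"hybrid"`.
#' @param hybrid_detailed_fraction Fraction of genes simulated in detail
#'   under `"hybrid"` (in `[0, 1]`).
#' @param detailed_genes Optional character vector of gene names forced into
#'   the detailed set (used e.g. before annotating attenuation control on a
#'   gene).
#' @param metabolism NTP renewal mode: `"constant"`, `"detailed"` or
#'   `"stacked"`.
#' @param seed Seed for the hybrid gene split.
#' @return A `polysim_model` with attribute `gene_info` (data frame: gene,
#'   detailed flag, transcript and protein species names).
#' @export
build_gene_expression <- function(genome, params = expression_params(),
                                  granularity = c("detailed", "aggregated", "hybrid"),
                                  hybrid_detailed_fraction = 0.05,
                                  detailed_genes = NULL,
                                  metabolism = c("constant", "detailed", "stacked"),
                                  seed = 1) {
  granularity <- match.arg(granularity)
  metabolism <- match.arg(metabolism)
  stopifnot(inherits(genome, "ps_genome"))
  if (hybrid_detailed_fraction < 0 || hybrid_detailed_fraction > 1)
    stop("hybrid_detailed_fraction must be in [0, 1]", call. = FALSE)
  genes <- genome$genes
  ng <- nrow(genes)
  detailed <- switch(granularity,
    detailed = rep(TRUE, ng),
    aggregated = rep(FALSE, ng),
    hybrid = with_seed(seed, {
      k <- round(hybrid_detailed_fraction * ng)
      idx <- if (k > 0) sample.int(ng, k) else integer()
      seq_len(ng) %in% idx
    }))
  if (!is.null(detailed_genes)) {
    miss <- setdiff(detailed_genes, genes$gene)
    if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "), call. = FALSE)
    detailed <- detailed | genes$gene %in% detailed_genes
  }

  cts <- params$counts
  tx <- params$transcription
  tl <- params$translation
  m <- ps_model()

  # shared pools
  ntp_buffered <- metabolism == "constant"
  m <- add_free_chemical(m, "RNAP", count = cts$rnap)
  m <- add_free_chemical(m, "ribosome", count = cts$ribosome)
  for (x in c("ATP", "CTP", "GTP", "UTP"))
    m <- add_free_chemical(m, x, count = cts$ntp, buffered = ntp_buffered)
  m <- add_free_chemical(m, "PPi")
  m <- add_free_chemical(m, "tRNA_bulk_c", count = cts$trna_bulk - cts$trna_bulk_uncharged)
  m <- add_free_chemical(m, "tRNA_bulk_u", count = cts$trna_bulk_uncharged)
  m <- add_free_chemical(m, "tRNA_tyr_c", count = cts$trna_tyr - cts$trna_tyr_uncharged)
  m <- add_free_chemical(m, "tRNA_tyr_u", count = cts$trna_tyr_uncharged)
  m <- add_free_chemical(m, "aa_bulk", count = cts$aa_bulk, buffered = TRUE)
  m <- add_free_chemical(m, "aa_tyr", count = cts$aa_tyr)
  m <- add_reaction(m, "charge_bulk", reactants = c(tRNA_bulk_u = 1, aa_bulk = 1),
                    products = c(tRNA_bulk_c = 1), k_forward = params$charging_k)
  m <- add_reaction(m, "charge_tyr", reactants = c(tRNA_tyr_u = 1, aa_tyr = 1),
                    products = c(tRNA_tyr_c = 1), k_forward = params$charging_k)

  # genome template and per-gene product species
  m <- add_sequence(m, "genome", genome$letters, copies = 1)
  for (i in seq_len(ng)) {
    g <- genes[i, ]
    m <- add_sequence(m, paste0("mRNA_", g$gene), transcript_letters(genome, i))
    m <- add_sequence(m, paste0("protein_", g$gene),
                      strrep("X", g$n_codons + 1L))
  }

  any_detailed <- any(detailed)
  if (any_detailed) {
    # generic transcription machinery
    for (cl in c("RNAP_loading", "RNAP_loaded", "RNAP_ready", "RNAP_term"))
      m <- add_bound_chemical(m, cl)
    m <- add_switch(m, "tx_terminator", "RNAP_loading", "RNAP_term")
    ntp_byp <- if (metabolism == "constant") {
      stats::setNames(rep("PPi", 4), c("ATP", "CTP", "GTP", "UTP"))
    } else {
      c(ATP = "PPi,AMP", CTP = "PPi,CMP", GTP = "PPi,GMP", UTP = "PPi,UMP")
    }
    if (metabolism != "constant") {
      for (x in c("AMP", "CMP", "GMP", "UMP")) m <- add_free_chemical(m, x)
      for (x in c("A", "C", "G", "U")) {
        nmp <- paste0(x, "MP"); ntp <- paste0(x, "TP")
        if (metabolism == "detailed") {
          m <- add_reaction(m, paste0("regen_", x), reactants = nmp, products = ntp,
                            k_forward = 10)
        } else {  # stacked: fires once a full stack of 100 has accumulated
          m <- add_reaction(m, paste0("regen_", x),
                            reactants = stats::setNames(100, nmp),
                            products = stats::setNames(100, ntp),
                            k_forward = 1e-200)
        }
      }
    }
    loaded_ntp <- unname(NTP_FOR_BASE[BASES])
    m <- add_loading(m, "tx_loading", "RNAP_loading",
                     data.frame(motif = BASES, loaded = loaded_ntp,
                                rate = tx$loading_eff[loaded_ntp] / cts$ntp,
                                post = "RNAP_loaded",
                                byproducts = unname(ntp_byp[loaded_ntp])))
    m <- add_reaction(m, "tx_polymerization", reactants = "RNAP_loaded",
                      products = "RNAP_ready", k_forward = tx$polymerization)
    m <- add_translocation(m, "tx_step", "RNAP_ready", "RNAP_loading",
                           step = 1, rate = tx$translocation)

    # generic translation machinery
    for (cl in c("R_loading", "R_loaded", "R_ready", "R_term"))
      m <- add_bound_chemical(m, cl)
    m <- add_switch(m, "tl_stop", "R_loading", "R_term")
    codons <- sense_codons()
    is_tyr <- codons %in% c("TAT", "TAC")
    charged_bulk <- cts$trna_bulk - cts$trna_bulk_uncharged
    charged_tyr <- cts$trna_tyr - cts$trna_tyr_uncharged
    m <- add_loading(m, "tl_loading", "R_loading",
                     data.frame(motif = codons,
                                loaded = ifelse(is_tyr, "tRNA_tyr_c", "tRNA_bulk_c"),
                                rate = ifelse(is_tyr,
                                              mean(tl$loading_eff) / charged_tyr,
                                              mean(tl$loading_eff) / charged_bulk),
                                post = "R_loaded",
                                byproducts = ifelse(is_tyr, "tRNA_tyr_u", "tRNA_bulk_u")))
    m <- add_reaction(m, "tl_transpeptidation", reactants = "R_loaded",
                      products = "R_ready", k_forward = tl$transpeptidation)
    m <- add_translocation(m, "tl_step", "R_ready", "R_loading",
                           step = 3, rate = tl$translocation)
  }

  # per-gene records
  tx_rel <- data.frame(family = character(), first = integer(), last = integer(),
                       product = character())
  tl_rel <- tx_rel
  for (i in seq_len(ng)) {
    g <- genes[i, ]
    mrna <- paste0("mRNA_", g$gene)
    prot <- paste0("protein_", g$gene)
    if (detailed[i]) {
      for (k in seq_len(g$tu_count))   # tandem promoters: TU multiplicity
        m <- add_binding_site(m, "promoter", "genome", g$promoter_first,
                              g$promoter_last, k_on = tx$k_on_promoter,
                              k_off = tx$k_off_promoter, reading_offset = g$tss)
      m <- add_switch_site(m, "genome", g$terminator, "tx_terminator")
      tx_rel <- rbind(tx_rel, data.frame(family = "promoter", first = g$terminator,
                                         last = g$terminator + 1L, product = mrna))
      rbs_fam <- paste0("rbs_", g$gene)
      m <- add_binding_site(m, rbs_fam, mrna, g$rbs_first, g$rbs_last,
                            k_on = tl$k_on_rbs, k_off = tl$k_off_rbs,
                            reading_offset = g$start_codon)
      m <- add_sequence_binding(m, paste0("bind_rbs_", g$gene), "ribosome",
                                "R_loading", rbs_fam)
      m <- add_switch_site(m, mrna, g$stop_codon, "tl_stop")
      tl_rel <- rbind(tl_rel, data.frame(family = rbs_fam, first = g$stop_codon,
                                         last = g$stop_codon + 1L, product = prot))
    } else {
      # aggregated: sequence-based binding, +50 nt hop off the site, then the
      # product in one step with the polymerase released
      pf <- paste0("prom_", g$gene)
      ca <- paste0("RNAPa_", g$gene); cb <- paste0("RNAPa2_", g$gene)
      m <- add_bound_chemical(m, ca)
      m <- add_bound_chemical(m, cb)
      for (k in seq_len(g$tu_count))
        m <- add_binding_site(m, pf, "genome", g$promoter_first, g$promoter_last,
                              k_on = tx$k_on_promoter, k_off = tx$k_off_promoter,
                              reading_offset = g$tss)
      m <- add_sequence_binding(m, paste0("bind_prom_", g$gene), "RNAP", ca, pf)
      # the +50 hop frees the promoter at elongation speed; the release step
      # carries the remaining elongation time plus ~1 s termination
      v_tx <- tx_cycle_speed(params)
      m <- add_translocation(m, paste0("tx_agg_move_", g$gene), ca, cb, step = 50,
                             rate = v_tx / 50)
      m <- add_release(m, paste0("tx_agg_rel_", g$gene), cb,
                       rate = 1 / ((g$mrna_len - 50) / v_tx + 1 / tx$termination),
                       freed = "RNAP",
                       products = data.frame(family = pf, first = 0,
                                             last = nchar(genome$letters),
                                             product = mrna))
      rf <- paste0("rbs_", g$gene)
      ra <- paste0("Ra_", g$gene); rb <- paste0("Ra2_", g$gene)
      m <- add_bound_chemical(m, ra)
      m <- add_bound_chemical(m, rb)
      m <- add_binding_site(m, rf, mrna, g$rbs_first, g$rbs_last,
                            k_on = tl$k_on_rbs, k_off = tl$k_off_rbs,
                            reading_offset = g$start_codon)
      m <- add_sequence_binding(m, paste0("bind_rbs_", g$gene), "ribosome", ra, rf)
      v_tl <- 3 * tl_cycle_speed(params)   # nt/s at codon stepping
      m <- add_translocation(m, paste0("tl_agg_move_", g$gene), ra, rb, step = 50,
                             rate = v_tl / 50)
      m <- add_release(m, paste0("tl_agg_rel_", g$gene), rb,
                       rate = 1 / (max(3 * (g$n_codons + 2L) - 50, 1) / v_tl +
                                     1 / tl$termination),
                       freed = "ribosome",
                       products = data.frame(family = rf, first = 0,
                                             last = g$mrna_len, product = prot))
    }
  }
  if (any_detailed) {
    if (nrow(tx_rel) == 0L) stop("internal: detailed set without release rows")
    m <- add_sequence_binding(m, "bind_promoter", "RNAP", "RNAP_loading", "promoter")
    m <- add_release(m, "tx_termination", "RNAP_term", rate = tx$termination,
                     freed = "RNAP", products = tx_rel)
    m <- add_release(m, "tl_termination", "R_term", rate = tl$termination,
                     freed = "ribosome", products = tl_rel)
  }
  m <- add_observable(m, c("RNAP", "ribosome", "tRNA_tyr_c", "tRNA_tyr_u",
                           paste0("mRNA_", genes$gene), paste0("protein_", genes$gene)))
  attr(m, "gene_info") <- data.frame(
    gene = genes$gene, detailed = detailed,
    transcript = paste0("mRNA_", genes$gene),
    protein = paste0("protein_", genes$gene),
    tss = genes$tss, terminator = genes$terminator,
    mrna_len = genes$mrna_len, n_codons = genes$n_codons,
    stringsAsFactors = FALSE)
  m
}

#' Extend a gene-expression model with tetracycline injection
#'
#' Tetracycline inhibits translation elongation by competing with charged
#' tRNAs for ribosomes in loading phase: a reversible sequestration of the
#' `R_loading` class (with a low dissociation rate) removes ribosomes from
#' the elongation cycle.  The extension only appends records -- free
#' tetracycline, the sequestered ribosome class, the sequestration reaction,
#' one injection event and a series of purification events that wash away
#' only the free pool, the bound form remaining.
#'
#' @param base_model A detailed-mode model from [build_gene_expression()].
#' @param injected_amount Molecules injected (the case studies use 20,000
#'   and 1,000,000).
#' @param t_inject Injection time in seconds (default 200).
#' @param t_purify First purification time (default 400); washes repeat
#'   every `purify_every` seconds, `purify_times` times in total.
#' @param purify_every,purify_times Purification schedule.
#' @param k_on,k_off Sequestration kinetics (1/s per molecule; low `k_off`
#'   makes sequestration long-lived).
#' @return The extended model.
#' @export
build_tetracycline_extension <- function(base_model, injected_amount,
                                         t_inject = 200, t_purify = 400,
                                         purify_every = 50, purify_times = 4,
                                         k_on = 1e-6, k_off = 0.01) {
  stopifnot_model(base_model)
  if (!"R_loading" %in% model_record_names(base_model, "BoundChemical"))
    stop("base model has no ribosome loading-phase class 'R_loading'; ",
         "build it in detailed mode", call. = FALSE)
  m <- base_model
  m <- add_free_chemical(m, "tetracycline")
  m <- add_bound_chemical(m, "R_tet")
  m <- add_reaction(m, "tet_sequestration",
                    reactants = c(tetracycline = 1, R_loading = 1),
                    products = c(R_tet = 1), k_forward = k_on, k_backward = k_off)
  if (injected_amount > 0)
    m <- add_event(m, t_inject, "ADD", "tetracycline", injected_amount)
  for (k in seq_len(purify_times))
    m <- add_event(m, t_purify + (k - 1) * purify_every, "REMOVE_FREE",
                   "tetracycline", max(injected_amount, 1))
  m <- add_observable(m, c("tetracycline", "R_tet"))
  attr(m, "gene_info") <- attr(base_model, "gene_info")
  m
}

#' Extend a gene-expression model with T-box attenuation
#'
#' Annotates a T-box regulatory site in the leader of the regulated gene:
#' an elongating polymerase landing on it switches to a paused `tbox_RNAP`
#' state.  Binding of an uncharged tyrosine tRNA resumes elongation;
#' binding of a charged tyrosine tRNA sends the polymerase to an aborting
#' state whose release produces an annotated aborted transcript instead of
#' the full-length messenger.  Tyrosine is depleted at `t_deplete` and
#' re-injected at `t_reinject`, so full-length transcripts accumulate only
#' while the charged fraction of the tyrosine tRNA pool is low.
#'
#' @param base_model Model from [build_gene_expression()]; the regulated
#'   gene must be in the detailed set (use `detailed_genes =` when building).
#' @param regulated_gene Gene name (e.g. `"g01"`).
#' @param t_deplete,t_reinject Tyrosine depletion / re-injection times (s).
#' @param reinject_amount Tyrosine molecules re-injected.
#' @param k_resume,k_uncharged_abort Rate constants of the competition of
#'   uncharged (resume) and charged (abort) tyrosine tRNA for the paused
#'   polymerase.
#' @return The extended model.
#' @export
build_tbox_extension <- function(base_model, regulated_gene,
                                 t_deplete = 200, t_reinject = 600,
                                 reinject_amount = 1e6,
                                 k_resume = 1e-3, k_uncharged_abort = 1e-3) {
  stopifnot_model(base_model)
  gi <- attr(base_model, "gene_info")
  if (is.null(gi) || !regulated_gene %in% gi$gene)
    stop("unknown regulated gene '", regulated_gene, "'", call. = FALSE)
  if (!gi$detailed[gi$gene == regulated_gene])
    stop("gene '", regulated_gene, "' is simulated in aggregated mode; ",
         "rebuild with detailed_genes = \"", regulated_gene,
         "\" so its transcription is simulated nucleotide by nucleotide",
         call. = FALSE)
  seqrec <- NULL
  for (r in base_model$records)
    if (r$kind == "Sequence" && r$name == "genome") { seqrec <- r; break }
  if (is.null(seqrec)) stop("base model has no 'genome' sequence", call. = FALSE)
  tss <- gi$tss[gi$gene == regulated_gene]
  tbox_pos <- tss + 12L   # inside the leader, upstream of the start codon

  m <- base_model
  m <- add_bound_chemical(m, "tbox_RNAP")
  m <- add_bound_chemical(m, "RNAP_abort")
  m <- add_switch(m, "tbox_switch", "RNAP_loading", "tbox_RNAP")
  m <- add_switch_site(m, "genome", tbox_pos, "tbox_switch")
  m <- add_sequence(m, paste0("aborted_", regulated_gene),
                    substr(seqrec$letters, tss + 1L, tbox_pos + 1L))
  m <- add_reaction(m, "tbox_resume",
                    reactants = c(tRNA_tyr_u = 1, tbox_RNAP = 1),
                    products = c(tRNA_tyr_u = 1, RNAP_loading = 1),
                    k_forward = k_resume)
  m <- add_reaction(m, "tbox_abort",
                    reactants = c(tRNA_tyr_c = 1, tbox_RNAP = 1),
                    products = c(tRNA_tyr_c = 1, RNAP_abort = 1),
                    k_forward = k_uncharged_abort)
  m <- add_release(m, "tbox_abort_release", "RNAP_abort", rate = 1,
                   freed = "RNAP",
                   products = data.frame(family = "promoter", first = tbox_pos,
                                         last = tbox_pos + 1L,
                                         product = paste0("aborted_", regulated_gene)))
  m <- add_event(m, t_deplete, "SET", "aa_tyr", 0)
  m <- add_event(m, t_reinject, "SET", "aa_tyr", reinject_amount)
  m <- add_observable(m, c("aa_tyr", paste0("aborted_", regulated_gene)))
  attr(m, "gene_info") <- gi
  m
}

#' Build a single-origin replication-fork model
#'
#' Leading-strand synthesis is simulated base per base (three-step cycle at
#' replication rates: translocation 750 /s limiting, polymerization
#' 10,000 /s, dNTP loading 1000-10,000 /s); the lagging strand is
#' represented by its polymerase-recruitment clock: with Okazaki fragments
#' of ~1000 bp and a fork speed of 750 bp/s a new polymerase is recruited
#' every 1.33 s, encoded as `|DNAP_free| x r_recruitment = 3/4`.
#'
#' @param template_length Leading-strand template length (nt).
#' @param params Parameter list from [expression_params()].
#' @param seed Seed for the random template.
#' @return A `polysim_model` observing the nascent strand count and the
#'   number of lagging-strand recruitments.
#' @export
build_replication_fork <- function(template_length = 5000,
                                   params = expression_params(), seed = 1) {
  rp <- params$replication
  letters <- with_seed(seed, random_letters(template_length))
  dntp <- params$counts$dntp
  m <- ps_model()
  m <- add_free_chemical(m, "DNAP", count = rp$dnap_copies)
  m <- add_free_chemical(m, "DNAP_engaged")
  for (x in c("dATP", "dCTP", "dGTP", "dTTP"))
    m <- add_free_chemical(m, x, count = dntp, buffered = TRUE)
  m <- add_free_chemical(m, "PPi_rep")
  m <- add_sequence(m, "chromosome", letters, copies = 1)
  m <- add_sequence(m, "nascent_strand", letters, copies = 0)
  for (cl in c("DNAP_loading", "DNAP_loaded", "DNAP_ready", "DNAP_term"))
    m <- add_bound_chemical(m, cl)
  m <- add_binding_site(m, "ori", "chromosome", 0, 10, k_on = 10, k_off = 0,
                        reading_offset = 0)
  m <- add_sequence_binding(m, "initiate", "DNAP", "DNAP_loading", "ori")
  dntp_for <- c(T = "dATP", A = "dTTP", C = "dGTP", G = "dCTP")
  m <- add_loading(m, "rep_loading", "DNAP_loading",
                   data.frame(motif = BASES, loaded = unname(dntp_for[BASES]),
                              rate = rp$loading_eff[unname(dntp_for[BASES])] / dntp,
                              post = "DNAP_loaded", byproducts = "PPi_rep"))
  m <- add_reaction(m, "rep_polymerization", reactants = "DNAP_loaded",
                    products = "DNAP_ready", k_forward = rp$polymerization)
  m <- add_translocation(m, "rep_step", "DNAP_ready", "DNAP_loading",
                         step = 1, rate = rp$translocation)
  m <- add_switch(m, "rep_end", "DNAP_loading", "DNAP_term")
  m <- add_switch_site(m, "chromosome", template_length - 1L, "rep_end")
  m <- add_release(m, "rep_finish", "DNAP_term", rate = 1, freed = "DNAP",
                   products = data.frame(family = "ori", first = 0,
                                         last = template_length,
                                         product = "nascent_strand"))
  # lagging strand: constant-propensity recruitment clock with total
  # propensity |DNAP_free| * r_recruitment = 3/4 (one Okazaki start / 1.33 s)
  balance <- recruitment_balance(0.75 / rp$recruitment_rate, rp$recruitment_rate)
  m <- add_free_chemical(m, "DNAP_lagging_pool", count = rp$dnap_copies,
                         buffered = TRUE)
  m <- add_reaction(m, "okazaki_recruitment",
                    reactants = "DNAP_lagging_pool", products = "DNAP_engaged",
                    k_forward = balance / rp$dnap_copies)
  m <- add_observable(m, c("nascent_strand", "DNAP_engaged"))
  m
}
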