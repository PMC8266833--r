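#' Compile a model into a runnable reaction system
#'
#' Instantiates the engine state for a [ps_model()]: chemical pools, template
#' sequences with their annotated sites, particle classes with their family
#' and template filters, the reaction channels, the propensity dependency
#' graph, and the sorted event schedule.  Counts given by `Init` records
#' override the counts declared on the records themselves; species without
#' any count default to zero.
#'
#' A `reaction_system` holds mutable simulation state: firing reactions or
#' running it advances that state.  [run_simulation()] called on a *model*
#' compiles a fresh system, which is what replicate runs should use.
#'
#' @param model A `polysim_model`.
#' @param seed Integer seed for the engine's random stream (used by
#'   interactive firing helpers; [run_simulation()] reseeds at run start).
#' @return An object of class `reaction_system`.
#' @export
compile_system <- function(model, seed = 1L) {
  stopifnot_model(model)
  if (length(model$records) == 0L) stop("model has no records", call. = FALSE)
  eng <- eng_new()

  recs <- model$records
  kinds <- vapply(recs, function(r) r$kind, character(1))

  # initial counts: last Init record wins
  init <- list()
  for (r in recs[kinds == "Init"]) init[[r$name]] <- r$count

  for (r in recs[kinds == "FreeChemical"]) {
    cnt <- if (!is.null(init[[r$name]])) init[[r$name]] else r$count
    eng_add_free(eng, r$name, cnt, r$buffered)
  }
  for (r in recs[kinds == "Sequence"]) {
    cnt <- if (!is.null(init[[r$name]])) init[[r$name]] else r$copies
    eng_add_seq(eng, r$name, r$letters, cnt)
  }
  for (r in recs[kinds == "BoundChemical"]) eng_add_bound(eng, r$name)
  for (r in recs[kinds == "BindingSite"]) {
    eng_add_site(eng, r$family, r$sequence, r$first, r$last, r$k_on, r$k_off,
                 r$reading_offset)
  }
  for (r in recs[kinds == "Switch"]) eng_add_switch(eng, r$name, r$input_class, r$output_class)
  for (r in recs[kinds == "SwitchSite"]) eng_add_switch_site(eng, r$sequence, r$position, r$switch)
  for (r in recs[kinds == "ChemicalReaction"]) {
    eng_add_chem(eng, r$name, names(r$reactants), unname(r$reactants),
                 names(r$products), unname(r$products), r$k_forward, r$k_backward)
  }
  for (r in recs[kinds == "SequenceBinding"]) {
    eng_add_binding(eng, r$name, r$free_form, r$bound_form, r$family)
  }
  for (r in recs[kinds == "Translocation"]) {
    eng_add_transloc(eng, r$name, r$mobile_class, r$post_class, r$step, r$rate)
  }
  for (r in recs[kinds == "Loading"]) {
    byp <- lapply(strsplit(r$byproducts, ",", fixed = TRUE), function(x) {
      x <- trimws(x)
      x[nzchar(x)]
    })
    if (length(byp) == 0L) byp <- rep(list(character()), length(r$motif))
    eng_add_loading(eng, r$name, r$loader_class, r$motif, r$loaded, r$rate, r$post, byp)
  }
  for (r in recs[kinds == "Release"]) {
    eng_add_release(eng, r$name, r$releasing_class, r$rate, r$freed,
                    r$family, r$first, r$last, r$product,
                    identical(r$on_unmatched, "warn"))
  }
  for (r in recs[kinds == "Event"]) eng_add_event(eng, r$time, r$event_kind, r$target, r$amount)

  eng_finalize(eng)
  eng_seed(eng, seed)
  structure(list(engine = eng, model = model, seed = seed),
            class = "reaction_system")
}

as_system <- function(x, seed = 1L) {
  if (inherits(x, "reaction_system")) x
  else if (inherits(x, "polysim_model")) compile_system(x, seed = seed)
  else stop("expected a polysim_model or reaction_system", call. = FALSE)
}

#' @export
print.reaction_system <- function(x, ...) {
  st <- eng_stats(x$engine)
  cat("<reaction_system>\n")
  cat("  reactions:", st$n_reactions, " channels:", st$n_channels, "\n")
  cat("  live particles:", st$live, "\n")
  invisible(x)
}

#' Number of available sites in a family
#'
#' Sums `copies - occupied` over all sites of a family; a site is occupied
#' while its bound unit has not yet translocated away from it.
#'
#' @param system A `reaction_system`.
#' @param family Site family name.
#' @return Non-negative integer count.
#' @export
available_site_count <- function(system, family) {
  eng_available(system$engine, family)
}

#' Molecule count of a species
#'
#' @param system A `reaction_system`.
#' @param name Species name: free chemical (count), sequence (copies) or
#'   bound chemical (number of particles).
#' @return Numeric scalar.
#' @export
chemical_count <- function(system, name) eng_count(system$engine, name)

#' All molecule counts
#'
#' @param system A `reaction_system`.
#' @return List with named numeric vectors `free`, `sequences`, `bound`.
#' @export
all_counts <- function(system) eng_counts(system$engine)

#' Overwrite the count of a free chemical or sequence
#'
#' @inheritParams chemical_count
#' @param count New non-negative count.
#' @export
set_chemical_count <- function(system, name, count) {
  eng_set_count(system$engine, name, count)
  invisible(system)
}

#' Particles of a bound chemical
#'
#' @param system A `reaction_system`.
#' @param class Bound chemical name.
#' @return Data frame with one row per particle: host sequence, 0-based
#'   position, origin-site family and whether the particle is still on its
#'   origin site.
#' @export
bound_members <- function(system, class) eng_members(system$engine, class)

#' Draw a uniformly distributed particle from a bound chemical
#'
#' @inheritParams bound_members
#' @return List describing the drawn particle; errors if the class is empty.
#' @export
sample_member <- function(system, class) eng_sample_member(system$engine, class)

#' Reassign a particle between bound-chemical classes
#'
#' Detaches a particle from `from_class` and re-attaches it to `to_class`,
#' keeping its template, position and origin state; all filters of both
#' classes are updated.
#'
#' @inheritParams bound_members
#' @param from_class,to_class Bound chemical names.
#' @param member 1-based index of the particle in `from_class` (internal
#'   order as returned by [bound_members()]); 0 draws one uniformly.
#' @export
reassign_unit <- function(system, from_class, to_class, member = 1L) {
  eng_reassign(system$engine, from_class, to_class, as.integer(member))
  invisible(system)
}

#' Current propensity of a reaction
#'
#' Recomputed from the live state.  Chemical reactions report both
#' directions, sequence bindings report forward binding and reverse
#' unbinding, loadings report the per-motif decomposition and its total.
#'
#' @param system A `reaction_system`.
#' @param name Reaction name.
#' @return A named list of rates.
#' @export
propensity <- function(system, name) eng_propensity(system$engine, name)

#' Fire one reaction by hand
#'
#' Executes a single firing of the named reaction using the engine's random
#' stream for all its internal choices (site, particle, ...).  Errors with
#' an impossible-reaction message when the propensity is zero.
#'
#' @param system A `reaction_system`.
#' @param name Reaction name.
#' @param direction `"forward"` or `"reverse"` where applicable.
#' @param motif For loadings: which motif row to fire.
#' @export
fire_reaction <- function(system, name, direction = "forward", motif = "") {
  eng_fire(system$engine, name, direction, motif)
  invisible(system)
}

#' Apply a timed-event action immediately
#'
#' @param system A `reaction_system`.
#' @param kind `"ADD"`, `"SET"` or `"REMOVE_FREE"`.
#' @param target Free chemical name.
#' @param amount Molecule count.
#' @export
apply_event <- function(system, kind, target, amount) {
  eng_apply_event(system$engine, kind, target, amount)
  invisible(system)
}

#' Audit the incremental bookkeeping against a scratch recomputation
#'
#' Recomputes, from the raw particle population alone, every incrementally
#' maintained structure -- site occupancy, family availability sums, family
#' filters (membership and unbinding-rate sums), template-filter partitions,
#' and particle conservation -- and errors on the first discrepancy.
#'
#' @param system A `reaction_system`.
#' @return `TRUE` invisibly when everything is consistent.
#' @export
check_consistency <- function(system) {
  invisible(eng_check(system$engine))
}

#' Engine bookkeeping statistics
#'
#' @param system A `reaction_system`.
#' @return List with particles created/destroyed/live and channel counts.
#' @export
system_stats <- function(system) eng_stats(system$engine)
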