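#' Create an empty model
#'
#' A `polysim_model` is an ordered collection of declarative records --
#' chemicals, template sequences, binding/switch sites and reactions -- that
#' together define a reaction system.  Records are added with the `add_*()`
#' family of functions and the model is turned into a runnable system with
#' [compile_system()] (or run directly with [run_simulation()], which compiles
#' a fresh system so that replicate runs are independent).
#'
#' @return An object of class `polysim_model`.
#' @seealso [add_free_chemical()], [compile_system()], [parse_model()]
#' @export
#' @examples
#' m <- ps_model()
#' m <- add_free_chemical(m, "A", count = 10)
#' m <- add_free_chemical(m, "B")
#' m <- add_reaction(m, "conv", reactants = "A", products = "B", k_forward = 1)
ps_model <- function() {
  structure(list(records = list()), class = "polysim_model")
}

ps_model_from_records <- function(records) {
  structure(list(records = records), class = "polysim_model")
}

#' @export
print.polysim_model <- function(x, ...) {
  kinds <- vapply(x$records, function(r) r$kind, character(1))
  cat("<polysim_model> with", length(x$records), "records\n")
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

stopifnot_model <- function(model) {
  if (!inherits(model, "polysim_model")) stop("not a polysim_model", call. = FALSE)
}

append_record <- function(model, rec) {
  stopifnot_model(model)
  model$records[[length(model$records) + 1L]] <- rec
  model
}

#' Declare a freely diffusing chemical
#'
#' Free chemicals are represented as population pools (a single molecule
#' count).  A buffered chemical keeps a constant count: it still gates
#' propensities but is never consumed or produced by a reaction firing
#' (timed events, in contrast, do change buffered pools).
#'
#' @param model A `polysim_model`.
#' @param name Unique species name.
#' @param count Initial molecule count (non-negative integer).
#' @param buffered Logical; keep the count constant across firings.
#' @return The extended model.
#' @export
add_free_chemical <- function(model, name, count = 0, buffered = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, count >= 0)
  append_record(model, list(kind = "FreeChemical", name = name,
                            count = as.numeric(count), buffered = isTRUE(buffered)))
}

#' Declare a bound chemical (particle class)
#'
#' A bound chemical is the external state class of sequence-bound particles,
#' e.g. "RNA polymerase in loading phase".  Reactions address classes;
#' individual particles carry their template, position and origin site.
#'
#' @inheritParams add_free_chemical
#' @return The extended model.
#' @export
add_bound_chemical <- function(model, name) {
  stopifnot(is.character(name), length(name) == 1L)
  append_record(model, list(kind = "BoundChemical", name = name))
}

#' Declare a template sequence
#'
#' A `ChemicalSequence` is a population of identical template copies with an
#' immutable letter string.  Binding sites and switch sites are annotated on
#' it; products of [add_release()] increment its copy number.
#'
#' @inheritParams add_free_chemical
#' @param letters Character scalar: the template string (e.g. over ACGT).
#' @param copies Initial population count of the sequence.
#' @return The extended model.
#' @export
add_sequence <- function(model, name, letters, copies = 0) {
  stopifnot(is.character(letters), length(letters) == 1L, nchar(letters) >= 1L,
            copies >= 0)
  append_record(model, list(kind = "Sequence", name = name, letters = letters,
                            copies = as.numeric(copies)))
}

#' Annotate a binding site on a sequence
#'
#' Sites are grouped into named families sharing binding kinetics from the
#' point of view of [add_sequence_binding()] reactions.  Coordinates are
#' 0-based and half-open: the site covers `[first, last)`.  A newly bound
#' unit starts reading at `reading_offset` (an absolute 0-based position).
#' Site availability is `copies - occupied`, where a site counts as occupied
#' while its unit has not yet translocated away.
#'
#' @inheritParams add_free_chemical
#' @param family Site family name (created on first use).
#' @param sequence Name of the host sequence.
#' @param first,last 0-based half-open interval on the sequence.
#' @param k_on Binding rate constant (1/s per free molecule per available site).
#' @param k_off Unbinding rate constant (1/s per unit still on its origin site).
#' @param reading_offset Absolute 0-based position where a bound unit starts.
#' @return The extended model.
#' @export
add_binding_site <- function(model, family, sequence, first, last,
                             k_on, k_off = 0, reading_offset = first) {
  stopifnot(k_on >= 0, k_off >= 0)
  append_record(model, list(kind = "BindingSite", family = family,
                            sequence = sequence, first = as.integer(first),
                            last = as.integer(last), k_on = k_on, k_off = k_off,
                            reading_offset = as.integer(reading_offset)))
}

#' Declare a switch between bound-chemical classes
#'
#' A switch reassigns a particle from `input_class` to `output_class` when a
#' translocation lands it exactly on an annotated switch-site position
#' ([add_switch_site()]).  Transcription terminators are the canonical use:
#' an elongating polymerase reaching the terminator switches to its
#' termination state.
#'
#' @inheritParams add_free_chemical
#' @param input_class,output_class Names of the two bound chemicals (distinct).
#' @return The extended model.
#' @export
add_switch <- function(model, name, input_class, output_class) {
  append_record(model, list(kind = "Switch", name = name,
                            input_class = input_class, output_class = output_class))
}

#' Annotate a switch site on a sequence
#'
#' @inheritParams add_free_chemical
#' @param sequence Name of the host sequence.
#' @param position 0-based position that triggers the switch on landing.
#' @param switch Name of the [add_switch()] record.
#' @return The extended model.
#' @export
add_switch_site <- function(model, sequence, position, switch) {
  append_record(model, list(kind = "SwitchSite", sequence = sequence,
                            position = as.integer(position), switch = switch))
}

#' Add a (possibly reversible) chemical reaction
#'
#' The propensity of each direction is the rate constant times the falling
#' factorial of each reactant count over its stoichiometry (so `A + A -> B`
#' with n molecules has propensity `k * n * (n - 1)`, and a reaction can
#' never fire with fewer molecules than it consumes).  At most one bound
#' chemical may appear on each side, with stoichiometry 1; when both sides
#' carry one, the fired particle keeps its template and position across the
#' reaction; a bound reactant with no bound product destroys and detaches
#' the particle.
#'
#' @inheritParams add_free_chemical
#' @param reactants,products Character vector of species names, or a named
#'   numeric vector of stoichiometries (names are species).
#' @param k_forward,k_backward Rate constants; `k_backward = 0` encodes an
#'   irreversible reaction.
#' @return The extended model.
#' @export
add_reaction <- function(model, name, reactants, products, k_forward, k_backward = 0) {
  norm <- function(x) {
    if (is.character(x)) stats::setNames(rep(1, length(x)), x)
    else if (is.numeric(x) && !is.null(names(x))) x
    else stop("reactants/products must be a character vector or named numeric vector",
              call. = FALSE)
  }
  r <- norm(reactants); p <- norm(products)
  stopifnot(k_forward >= 0, k_backward >= 0)
  append_record(model, list(kind = "ChemicalReaction", name = name,
                            reactants = r, products = p,
                            k_forward = k_forward, k_backward = k_backward))
}

#' Add a sequence-binding reaction
#'
#' Binds a free chemical to any available site of a family, creating a
#' particle of class `bound_form` at the site's reading offset.  The forward
#' propensity is `count(free_form) * sum_sites k_on * available(site)`; the
#' reverse (unbinding) propensity sums `k_off` over the particles of
#' `bound_form` that are still on the site they originally bound to.
#'
#' @inheritParams add_free_chemical
#' @param free_form Name of the free chemical that binds.
#' @param bound_form Name of the bound chemical the new particle joins.
#' @param family Binding-site family.
#' @return The extended model.
#' @export
add_sequence_binding <- function(model, name, free_form, bound_form, family) {
  append_record(model, list(kind = "SequenceBinding", name = name,
                            free_form = free_form, bound_form = bound_form,
                            family = family))
}

#' Add a translocation reaction
#'
#' Moves a uniformly chosen particle of `mobile_class` forward by `step`
#' positions (1 for nucleotide stepping, 3 for codon stepping) and reassigns
#' it to `post_class`.  The first translocation releases the particle's
#' origin binding site.  If the landing position carries a switch site whose
#' input class is `post_class`, the particle is immediately switched; skipped
#' intermediate positions are not scanned, so switch sites for codon-stepping
#' processes must sit on the reading frame.
#'
#' @inheritParams add_free_chemical
#' @param mobile_class,post_class Bound chemical before/after the move.
#' @param step Positions advanced per firing (>= 1).
#' @param rate Rate (1/s per particle).
#' @return The extended model.
#' @export
add_translocation <- function(model, name, mobile_class, post_class, step, rate) {
  stopifnot(step >= 1, rate >= 0)
  append_record(model, list(kind = "Translocation", name = name,
                            mobile_class = mobile_class, post_class = post_class,
                            step = as.integer(step), rate = rate))
}

#' Add a template-directed loading reaction
#'
#' Loading consumes a free chemical chosen by the motif the particle is
#' currently reading (e.g. the nucleotide complementary to the template
#' base, or the charged tRNA matching the codon).  Each motif row fires at
#' `rate * count(loaded) * #particles reading that motif`; at firing a
#' uniform particle from the motif's partition is moved to `post_class` and
#' the byproducts are released.  All motifs of one loading (and of all
#' loadings sharing a loader class) must have the same length.
#'
#' @inheritParams add_free_chemical
#' @param loader_class Bound chemical whose particles load.
#' @param table A data frame with columns `motif`, `loaded`, `rate`, `post`,
#'   and optionally `byproducts` (comma-separated names, possibly empty).
#' @return The extended model.
#' @export
add_loading <- function(model, name, loader_class, table) {
  stopifnot(is.data.frame(table),
            all(c("motif", "loaded", "rate", "post") %in% names(table)))
  byp <- if ("byproducts" %in% names(table)) as.character(table$byproducts)
         else rep("", nrow(table))
  append_record(model, list(kind = "Loading", name = name,
                            loader_class = loader_class,
                            motif = as.character(table$motif),
                            loaded = as.character(table$loaded),
                            rate = as.numeric(table$rate),
                            post = as.character(table$post),
                            byproducts = byp))
}

#' Add a release reaction
#'
#' Destroys a uniformly chosen particle of `releasing_class`, frees the
#' listed chemicals (e.g. the polymerase), and creates one copy of the
#' product sequence selected by the particle's origin-site family and its
#' current position: the row `(family, [first, last))` that contains the
#' position wins.  Product intervals of one family must be disjoint.  A
#' particle whose position matches no interval raises an error unless
#' `on_unmatched = "warn"`.
#'
#' @inheritParams add_free_chemical
#' @param releasing_class Bound chemical whose particles are released.
#' @param rate Rate (1/s per particle).
#' @param freed Character vector of free chemicals released per firing.
#' @param products Data frame with columns `family`, `first`, `last`,
#'   `product` (`NULL` for a product-less release).
#' @param on_unmatched `"error"` (default) or `"warn"`.
#' @return The extended model.
#' @export
add_release <- function(model, name, releasing_class, rate, freed = character(),
                        products = NULL, on_unmatched = c("error", "warn")) {
  on_unmatched <- match.arg(on_unmatched)
  if (is.null(products)) {
    products <- data.frame(family = character(), first = integer(),
                           last = integer(), product = character())
  }
  stopifnot(all(c("family", "first", "last", "product") %in% names(products)))
  append_record(model, list(kind = "Release", name = name,
                            releasing_class = releasing_class, rate = rate,
                            freed = as.character(freed),
                            family = as.character(products$family),
                            first = as.integer(products$first),
                            last = as.integer(products$last),
                            product = as.character(products$product),
                            on_unmatched = on_unmatched))
}

#' Schedule a timed event
#'
#' Events modify free pools at fixed times during a run: `ADD` increments a
#' pool, `SET` overwrites it, and `REMOVE_FREE` clamps `count - amount` at
#' zero, touching only the free pool (sequestered bound complexes are
#' untouched, as in a wash-out that removes only free antibiotic).
#'
#' @inheritParams add_free_chemical
#' @param time Event time in seconds (non-negative).
#' @param kind One of `"ADD"`, `"SET"`, `"REMOVE_FREE"`.
#' @param target Name of the free chemical.
#' @param amount Molecule count used by the event.
#' @return The extended model.
#' @export
add_event <- function(model, time, kind = c("ADD", "SET", "REMOVE_FREE"),
                      target, amount) {
  kind <- match.arg(kind)
  stopifnot(time >= 0, amount >= 0)
  append_record(model, list(kind = "Event", time = as.numeric(time),
                            event_kind = kind, target = target,
                            amount = as.numeric(amount)))
}

#' Override the initial count of a chemical or sequence
#'
#' @inheritParams add_free_chemical
#' @param count New initial count (free chemical) or copy number (sequence).
#' @return The extended model.
#' @export
set_initial_count <- function(model, name, count) {
  stopifnot(count >= 0)
  append_record(model, list(kind = "Init", name = name, count = as.numeric(count)))
}

#' Select observables to log during a run
#'
#' @inheritParams add_free_chemical
#' @param names Character vector of species (free chemicals, sequences or
#'   bound chemicals) whose counts are written to the trajectory.
#' @return The extended model.
#' @export
add_observable <- function(model, names) {
  append_record(model, list(kind = "Observe", names = as.character(names)))
}

#' Read a motif from a template string
#'
#' Returns the `length` letters starting at 0-based `position`, or `NA` when
#' the window overruns the end of the sequence (a particle that close to the
#' end has no readable motif and cannot load).
#'
#' @param letters Template string.
#' @param position 0-based position of the first letter.
#' @param length Motif length (>= 1).
#' @return A character scalar, or `NA_character_` on overrun.
#' @export
#' @examples
#' read_motif("ATGC", 0, 3)  # "ATG"
#' read_motif("ATGC", 3, 3)  # NA: overruns the end
read_motif <- function(letters, position, length) {
  stopifnot(is.character(letters), base::length(letters) == 1L, length >= 1)
  if (position < 0) stop("position must be non-negative", call. = FALSE)
  if (position + length > nchar(letters)) return(NA_character_)
  substr(letters, position + 1L, position + length)
}

model_observables <- function(model) {
  obs <- character()
  for (r in model$records) if (r$kind == "Observe") obs <- c(obs, r$names)
  unique(obs)
}

model_record_names <- function(model, kinds) {
  out <- character()
  for (r in model$records) if (r$kind %in% kinds && !is.null(r$name)) out <- c(out, r$name)
  out
}
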