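#' @useDynLib polysim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Model-definition dialect.
#
# Line-based, whitespace-delimited records; `#` starts a comment; lines that
# are blank after comment stripping are separators.  Multi-line tables
# (Loading, Release) start with a header record and are terminated by a
# blank line or end of file.  A model directory holds one or more `.in`
# files, read in lexicographic order; every name must be declared before it
# is used, across the concatenation of all files.
#
#   FreeChemical <name> [buffered]
#   BoundChemical <name>
#   Sequence <name> <letters>
#   Sequence <name> fasta <file> <record-id>
#   BindingSite <family> <sequence> <first> <last> <k_on> <k_off> <offset>
#   Switch <name> <input_class> <output_class>
#   SwitchSite <sequence> <position> <switch>
#   ChemicalReaction <name> <k_f> <k_b> : <stoich> <species> ... -> <stoich> <species> ...
#   SequenceBinding <name> <free_form> <bound_form> <family>
#   Translocation <name> <mobile> <post> <step> <rate>
#   Loading <name> <loader_class>
#     <motif> <loaded> <rate> <post_class> <byproducts-or-->
#   Release <name> <class> <rate> <freed-or-->
#     <family> <first> <last> <product>
#   Event <time> <ADD|SET|REMOVE_FREE> <target> <amount>
#   Init <name> <count>
#   Observe <name> [<name> ...]

parse_err <- function(file, lineno, msg) {
  stop(sprintf("%s:%d: %s", file, lineno, msg), call. = FALSE)
}

split_tokens <- function(line) {
  line <- sub("#.*$", "", line)
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  tok[nzchar(tok)]
}

comma_list <- function(x) {
  if (identical(x, "-") || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Parse a model directory
#'
#' Reads every `.in` file of a directory in lexicographic order and links
#' the records into a single [ps_model()].  Extension by adding one more
#' file leaves the records of the existing files untouched, which is how
#' case-study overlays (e.g. an antibiotic-injection file) are layered onto
#' a base model.  Every referenced name must be declared earlier in the
#' concatenation; parse errors name the offending file and 1-based line.
#'
#' @param directory Path to a model directory containing `>= 1` `.in` file.
#' @return A `polysim_model`.
#' @export
parse_model <- function(directory) {
  if (!dir.exists(directory)) stop("no such model directory: ", directory, call. = FALSE)
  files <- sort(list.files(directory, pattern = "\\.in$", full.names = TRUE))
  if (length(files) == 0L)
    stop("model directory contains no .in files: ", directory, call. = FALSE)

  records <- vector("list", 1024L)
  nrec <- 0L
  push <- function(rec) {
    nrec <<- nrec + 1L
    if (nrec > length(records)) records[[2L * nrec]] <<- NULL
    records[[nrec]] <<- rec
  }
  declared <- new.env(parent = emptyenv())   # species + switches
  families <- new.env(parent = emptyenv())
  rxnames <- new.env(parent = emptyenv())
  seqlen <- new.env(parent = emptyenv())

  decl <- function(name, file, ln) {
    if (!is.null(declared[[name]]))
      parse_err(file, ln, sprintf("duplicate declaration of '%s'", name))
    declared[[name]] <- TRUE
  }
  need <- function(name, file, ln, what = "name") {
    if (is.null(declared[[name]]))
      parse_err(file, ln, sprintf("reference to undeclared %s '%s'", what, name))
  }
  need_fam <- function(name, file, ln) {
    if (is.null(families[[name]]))
      parse_err(file, ln, sprintf("reference to undeclared site family '%s'", name))
  }
  decl_rxn <- function(name, file, ln) {
    if (!is.null(rxnames[[name]]))
      parse_err(file, ln, sprintf("duplicate reaction name '%s'", name))
    rxnames[[name]] <- TRUE
  }
  num <- function(x, file, ln, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) parse_err(file, ln, sprintf("malformed %s '%s'", what, x))
    v
  }

  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    fname <- basename(f)
    i <- 1L
    n <- length(lines)
    while (i <= n) {
      tok <- split_tokens(lines[i])
      ln <- i
      i <- i + 1L
      if (length(tok) == 0L) next
      kind <- tok[1]
      arg <- tok[-1]
      if (kind == "FreeChemical") {
        if (length(arg) < 1L || length(arg) > 2L) parse_err(fname, ln, "usage: FreeChemical <name> [buffered]")
        buffered <- length(arg) == 2L
        if (buffered && arg[2] != "buffered") parse_err(fname, ln, "second field must be 'buffered'")
        decl(arg[1], fname, ln)
        push(list(kind = "FreeChemical", name = arg[1], count = 0, buffered = buffered))
      } else if (kind == "BoundChemical") {
        if (length(arg) != 1L) parse_err(fname, ln, "usage: BoundChemical <name>")
        decl(arg[1], fname, ln)
        push(list(kind = "BoundChemical", name = arg[1]))
      } else if (kind == "Sequence") {
        if (length(arg) == 2L) {
          letters <- toupper(arg[2])
        } else if (length(arg) == 4L && arg[2] == "fasta") {
          fp <- file.path(directory, arg[3])
          if (!file.exists(fp)) parse_err(fname, ln, paste0("FASTA file not found: ", arg[3]))
          fa <- Biostrings::readDNAStringSet(fp)
          ids <- sub("\\s.*$", "", names(fa))
          k <- match(arg[4], ids)
          if (is.na(k)) parse_err(fname, ln, sprintf("record '%s' not in %s", arg[4], arg[3]))
          letters <- as.character(fa[[k]])
        } else parse_err(fname, ln, "usage: Sequence <name> <letters> | Sequence <name> fasta <file> <record>")
        decl(arg[1], fname, ln)
        seqlen[[arg[1]]] <- nchar(letters)
        push(list(kind = "Sequence", name = arg[1], letters = letters, copies = 0))
      } else if (kind == "BindingSite") {
        if (length(arg) != 7L) parse_err(fname, ln, "usage: BindingSite <family> <sequence> <first> <last> <k_on> <k_off> <offset>")
        need(arg[2], fname, ln, "sequence")
        first <- num(arg[3], fname, ln, "first"); last <- num(arg[4], fname, ln, "last")
        L <- seqlen[[arg[2]]]
        if (!is.null(L) && (first < 0 || first >= last || last > L))
          parse_err(fname, ln, sprintf("site [%d,%d) out of bounds for '%s' (length %d)",
                                       first, last, arg[2], L))
        families[[arg[1]]] <- TRUE
        push(list(kind = "BindingSite", family = arg[1], sequence = arg[2],
                  first = as.integer(first), last = as.integer(last),
                  k_on = num(arg[5], fname, ln, "k_on"),
                  k_off = num(arg[6], fname, ln, "k_off"),
                  reading_offset = as.integer(num(arg[7], fname, ln, "offset"))))
      } else if (kind == "Switch") {
        if (length(arg) != 3L) parse_err(fname, ln, "usage: Switch <name> <input> <output>")
        need(arg[2], fname, ln, "bound chemical"); need(arg[3], fname, ln, "bound chemical")
        decl(arg[1], fname, ln)
        push(list(kind = "Switch", name = arg[1], input_class = arg[2], output_class = arg[3]))
      } else if (kind == "SwitchSite") {
        if (length(arg) != 3L) parse_err(fname, ln, "usage: SwitchSite <sequence> <position> <switch>")
        need(arg[1], fname, ln, "sequence"); need(arg[3], fname, ln, "switch")
        push(list(kind = "SwitchSite", sequence = arg[1],
                  position = as.integer(num(arg[2], fname, ln, "position")), switch = arg[3]))
      } else if (kind == "ChemicalReaction") {
        sep <- which(arg == ":")
        if (length(sep) != 1L || sep != 4L)
          parse_err(fname, ln, "usage: ChemicalReaction <name> <k_f> <k_b> : <stoich> <sp> ... -> <stoich> <sp> ...")
        decl_rxn(arg[1], fname, ln)
        body <- arg[5:length(arg)]
        arrow <- which(body == "->")
        if (length(arrow) != 1L) parse_err(fname, ln, "missing '->'")
        parse_side <- function(v) {
          if (length(v) %% 2L != 0L) parse_err(fname, ln, "species must be preceded by stoichiometry")
          if (length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
          st <- v[seq(1, length(v), by = 2)]
          sp <- v[seq(2, length(v), by = 2)]
          for (s in sp) need(s, fname, ln, "species")
          stats::setNames(vapply(st, num, numeric(1), file = fname, ln = ln, what = "stoichiometry"), sp)
        }
        lhs <- parse_side(if (arrow > 1L) body[1:(arrow - 1L)] else character())
        rhs <- parse_side(if (arrow < length(body)) body[(arrow + 1L):length(body)] else character())
        push(list(kind = "ChemicalReaction", name = arg[1], reactants = lhs, products = rhs,
                  k_forward = num(arg[2], fname, ln, "k_f"),
                  k_backward = num(arg[3], fname, ln, "k_b")))
      } else if (kind == "SequenceBinding") {
        if (length(arg) != 4L) parse_err(fname, ln, "usage: SequenceBinding <name> <free> <bound> <family>")
        decl_rxn(arg[1], fname, ln)
        need(arg[2], fname, ln, "free chemical"); need(arg[3], fname, ln, "bound chemical")
        need_fam(arg[4], fname, ln)
        push(list(kind = "SequenceBinding", name = arg[1], free_form = arg[2],
                  bound_form = arg[3], family = arg[4]))
      } else if (kind == "Translocation") {
        if (length(arg) != 5L) parse_err(fname, ln, "usage: Translocation <name> <mobile> <post> <step> <rate>")
        decl_rxn(arg[1], fname, ln)
        need(arg[2], fname, ln, "bound chemical"); need(arg[3], fname, ln, "bound chemical")
        push(list(kind = "Translocation", name = arg[1], mobile_class = arg[2],
                  post_class = arg[3], step = as.integer(num(arg[4], fname, ln, "step")),
                  rate = num(arg[5], fname, ln, "rate")))
      } else if (kind == "Loading") {
        if (length(arg) != 2L) parse_err(fname, ln, "usage: Loading <name> <loader_class>")
        decl_rxn(arg[1], fname, ln)
        need(arg[2], fname, ln, "bound chemical")
        motif <- loaded <- post <- byp <- character(); rate <- numeric()
        while (i <= n) {
          raw <- lines[i]
          if (!nzchar(trimws(raw))) { i <- i + 1L; break }   # blank line ends table
          rtok <- split_tokens(raw)
          rln <- i
          i <- i + 1L
          if (length(rtok) == 0L) next                        # comment-only line
          if (length(rtok) != 5L)
            parse_err(fname, rln, "loading row: <motif> <loaded> <rate> <post> <byproducts-or-->")
          need(rtok[2], fname, rln, "free chemical"); need(rtok[4], fname, rln, "bound chemical")
          for (b in comma_list(rtok[5])) need(b, fname, rln, "free chemical")
          motif <- c(motif, toupper(rtok[1])); loaded <- c(loaded, rtok[2])
          rate <- c(rate, num(rtok[3], fname, rln, "rate")); post <- c(post, rtok[4])
          byp <- c(byp, if (rtok[5] == "-") "" else rtok[5])
        }
        if (length(motif) == 0L) parse_err(fname, ln, "loading table is empty")
        push(list(kind = "Loading", name = arg[1], loader_class = arg[2],
                  motif = motif, loaded = loaded, rate = rate, post = post,
                  byproducts = byp))
      } else if (kind == "Release") {
        if (length(arg) != 4L) parse_err(fname, ln, "usage: Release <name> <class> <rate> <freed-or-->")
        decl_rxn(arg[1], fname, ln)
        need(arg[2], fname, ln, "bound chemical")
        freed <- comma_list(arg[4])
        for (b in freed) need(b, fname, ln, "free chemical")
        fam <- prod_ <- character(); first <- last <- integer()
        while (i <= n) {
          raw <- lines[i]
          if (!nzchar(trimws(raw))) { i <- i + 1L; break }
          rtok <- split_tokens(raw)
          rln <- i
          i <- i + 1L
          if (length(rtok) == 0L) next
          if (length(rtok) != 4L)
            parse_err(fname, rln, "release row: <family> <first> <last> <product>")
          need_fam(rtok[1], fname, rln); need(rtok[4], fname, rln, "sequence")
          fam <- c(fam, rtok[1])
          first <- c(first, as.integer(num(rtok[2], fname, rln, "first")))
          last <- c(last, as.integer(num(rtok[3], fname, rln, "last")))
          prod_ <- c(prod_, rtok[4])
        }
        push(list(kind = "Release", name = arg[1], releasing_class = arg[2],
                  rate = num(arg[3], fname, ln, "rate"), freed = freed,
                  family = fam, first = first, last = last, product = prod_,
                  on_unmatched = "error"))
      } else if (kind == "Event") {
        if (length(arg) != 4L) parse_err(fname, ln, "usage: Event <time> <kind> <target> <amount>")
        if (!arg[2] %in% c("ADD", "SET", "REMOVE_FREE"))
          parse_err(fname, ln, sprintf("unknown event kind '%s'", arg[2]))
        need(arg[3], fname, ln, "free chemical")
        push(list(kind = "Event", time = num(arg[1], fname, ln, "time"),
                  event_kind = arg[2], target = arg[3],
                  amount = num(arg[4], fname, ln, "amount")))
      } else if (kind == "Init") {
        if (length(arg) != 2L) parse_err(fname, ln, "usage: Init <name> <count>")
        need(arg[1], fname, ln, "species")
        push(list(kind = "Init", name = arg[1], count = num(arg[2], fname, ln, "count")))
      } else if (kind == "Observe") {
        if (length(arg) < 1L) parse_err(fname, ln, "usage: Observe <name> [...]")
        for (s in arg) need(s, fname, ln, "species")
        push(list(kind = "Observe", names = arg))
      } else {
        parse_err(fname, ln, sprintf("unknown record kind '%s'", kind))
      }
    }
  }
  ps_model_from_records(records[seq_len(nrec)])
}

# ---------------------------------------------------------------------------

fmt_num <- function(x) {
  # full double precision for non-integers, so rate constants survive a
  # round trip bit for bit
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
         trimws(formatC(x, digits = 17, format = "g")))
}

#' Serialize a model to dialect text
#'
#' Emits the records of a model (or of the model behind a compiled system)
#' in the dialect read by [parse_model()], declarations before uses:
#' chemicals and sequences first, then sites and switches, then reactions,
#' events, initial counts and observables.  The round trip
#' `parse(serialize(parse(x)))` is structurally identical to `parse(x)`.
#'
#' @param x A `polysim_model` or `reaction_system`.
#' @return Character vector of dialect lines.
#' @export
serialize_model <- function(x) {
  model <- if (inherits(x, "reaction_system")) x$model else x
  stopifnot_model(model)
  recs <- model$records
  kinds <- vapply(recs, function(r) r$kind, character(1))
  out <- character()
  emit <- function(...) out <<- c(out, paste(...))
  for (r in recs[kinds == "FreeChemical"])
    emit("FreeChemical", r$name, if (r$buffered) "buffered" else NULL)
  for (r in recs[kinds == "BoundChemical"]) emit("BoundChemical", r$name)
  for (r in recs[kinds == "Sequence"]) emit("Sequence", r$name, r$letters)
  for (r in recs[kinds == "BindingSite"])
    emit("BindingSite", r$family, r$sequence, r$first, r$last,
         fmt_num(r$k_on), fmt_num(r$k_off), r$reading_offset)
  for (r in recs[kinds == "Switch"]) emit("Switch", r$name, r$input_class, r$output_class)
  for (r in recs[kinds == "SwitchSite"]) emit("SwitchSite", r$sequence, r$position, r$switch)
  for (r in recs[kinds == "ChemicalReaction"]) {
    side <- function(v) paste(rbind(fmt_num(unname(v)), names(v)), collapse = " ")
    emit("ChemicalReaction", r$name, fmt_num(r$k_forward), fmt_num(r$k_backward), ":",
         side(r$reactants), "->", side(r$products))
  }
  for (r in recs[kinds == "SequenceBinding"])
    emit("SequenceBinding", r$name, r$free_form, r$bound_form, r$family)
  for (r in recs[kinds == "Translocation"])
    emit("Translocation", r$name, r$mobile_class, r$post_class, r$step, fmt_num(r$rate))
  for (r in recs[kinds == "Loading"]) {
    emit("Loading", r$name, r$loader_class)
    for (k in seq_along(r$motif))
      emit(r$motif[k], r$loaded[k], fmt_num(r$rate[k]), r$post[k],
           if (nzchar(r$byproducts[k])) r$byproducts[k] else "-")
    out <- c(out, "")
  }
  for (r in recs[kinds == "Release"]) {
    emit("Release", r$name, r$releasing_class, fmt_num(r$rate),
         if (length(r$freed)) paste(r$freed, collapse = ",") else "-")
    for (k in seq_along(r$family))
      emit(r$family[k], r$first[k], r$last[k], r$product[k])
    out <- c(out, "")
  }
  for (r in recs[kinds == "Event"])
    emit("Event", fmt_num(r$time), r$event_kind, r$target, fmt_num(r$amount))
  for (r in recs[kinds == "FreeChemical"]) if (r$count > 0) emit("Init", r$name, fmt_num(r$count))
  for (r in recs[kinds == "Sequence"]) if (r$copies > 0) emit("Init", r$name, fmt_num(r$copies))
  for (r in recs[kinds == "Init"]) emit("Init", r$name, fmt_num(r$count))
  for (r in recs[kinds == "Observe"]) emit("Observe", paste(r$names, collapse = " "))
  out
}

#' Write a model directory
#'
#' @param model A `polysim_model`.
#' @param directory Output directory (created if needed).
#' @param file Name of the `.in` file to write.
#' @return The directory, invisibly.
#' @export
write_model <- function(model, directory, file = "model.in") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeLines(serialize_model(model), file.path(directory, file))
  invisible(directory)
}

#' Write a trajectory as tab-separated text
#'
#' Column 1 is time (6 significant digits); the remaining columns are the
#' observed molecule counts, printed as integers.
#'
#' @param trajectory A [run_simulation()] result.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(nrow(trajectory) >= 1L)
  df <- as.data.frame(trajectory)
  df$time <- signif(df$time, 6)
  for (j in setdiff(names(df), "time")) df[[j]] <- format(df[[j]], scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path TSV file.
#' @return Data frame with a `time` column and one column per observable.
#' @export
read_trajectory <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write run metadata as a key-value sidecar file
#'
#' @param path Output file.
#' @param t_end,seed,solver,log_period Run configuration.
#' @param extra Named character vector of additional keys.
#' @export
write_run_metadata <- function(path, t_end, seed, solver, log_period, extra = NULL) {
  kv <- c(package = as.character(utils::packageVersion("polysim")),
          r_version = paste(R.version$major, R.version$minor, sep = "."),
          t_end = as.character(t_end), seed = as.character(seed),
          solver = solver, log_period = as.character(log_period), extra)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}
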