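# Synthetic genome generation: a stand-in for a real bacterial annotation
# set, with the same per-gene feature classes (promoter, transcription start,
# terminator, ribosome binding site, start/stop codons).

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

random_letters <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Fixed gene anatomy (all coordinates 0-based):
#   promoter        genome [B, B+10), transcription start at B+10
#   transcript      genome [tss, tss+mrna_len); the terminator is its last base
#   on the transcript: leader [0,20) carrying the RBS at [5,11),
#   start codon ATG at 20, n_codons sense codons, stop codon TAA,
#   10 nt trailer ending at the terminator.
GENE_OVERHEAD <- 10L + 20L + 3L + 3L + 10L   # everything except the codon body
LEADER_LEN <- 20L
RBS_FIRST <- 5L
RBS_LAST <- 11L

#' Generate a synthetic annotated genome
#'
#' Draws random gene sequences over ACGT with well-formed annotations:
#' a 10 nt promoter, transcription start, a leader carrying the ribosome
#' binding site, an ATG start codon, a stop-free codon body, a TAA stop
#' codon, a short trailer and a terminator at the transcript end.  Genes are
#' separated by 20 nt spacers.  Coding regions are sampled codon-wise from
#' the 61 sense codons so that a translating ribosome never encounters an
#' unreadable motif before its annotated stop position.
#'
#' Each gene carries a transcription-unit multiplicity `tu_count` (1-4):
#' the number of equal-strength tandem promoters driving it, emulating
#' genes that belong to several transcription units.  Expected transcript
#' and protein output scale with this multiplicity, which is what makes
#' per-gene outputs comparable across model granularities.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_range Two integers: min/max total gene span in nt
#'   (promoter through terminator); must allow at least one codon.
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @return A `ps_genome`: list with `letters` (genome string), `genes`
#'   (data frame of annotations, genome coordinates 0-based; RBS and codon
#'   positions are transcript-relative), and `seed`.
#' @export
#' @examples
#' g <- synthesize_genome(3, c(300, 400), seed = 42)
#' g$genes[, c("gene", "tss", "terminator", "n_codons")]
synthesize_genome <- function(n_genes, gene_length_range = c(300, 600), seed = 1) {
  stopifnot(n_genes >= 1)
  gene_length_range <- as.integer(gene_length_range)
  if (length(gene_length_range) != 2L ||
      gene_length_range[1] > gene_length_range[2] ||
      gene_length_range[1] < GENE_OVERHEAD + 3L)
    stop(sprintf("degenerate gene length range: need %d <= min <= max",
                 GENE_OVERHEAD + 3L), call. = FALSE)
  with_seed(seed, {
    spacer <- 20L
    sense <- sense_codons()
    parts <- character(2L * n_genes + 1L)
    parts[1] <- random_letters(spacer)
    offset <- spacer
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      span <- sample(seq(gene_length_range[1], gene_length_range[2]), 1L)
      n_cod <- (span - GENE_OVERHEAD) %/% 3L
      promoter <- random_letters(10L)
      leader <- random_letters(LEADER_LEN)
      body <- paste(sample(sense, n_cod, replace = TRUE), collapse = "")
      trailer <- random_letters(10L)
      gene_seq <- paste0(promoter, leader, "ATG", body, "TAA", trailer)
      gene_len <- nchar(gene_seq)
      mrna_len <- gene_len - 10L
      tss <- offset + 10L
      rows[[i]] <- data.frame(
        gene = sprintf("g%02d", i),
        tu_count = sample(1:4, 1L),
        promoter_first = offset, promoter_last = offset + 10L,
        tss = tss,
        terminator = tss + mrna_len - 1L,
        mrna_len = mrna_len,
        rbs_first = RBS_FIRST, rbs_last = RBS_LAST,
        start_codon = LEADER_LEN,
        stop_codon = LEADER_LEN + 3L + 3L * n_cod,
        n_codons = n_cod,
        stringsAsFactors = FALSE)
      parts[2L * i] <- gene_seq
      parts[2L * i + 1L] <- random_letters(spacer)
      offset <- offset + gene_len + spacer
    }
    genes <- do.call(rbind, rows)
    genome <- structure(list(letters = paste(parts, collapse = ""),
                             genes = genes, seed = seed),
                        class = "ps_genome")
    validate_genome(genome)
    genome
  })
}

validate_genome <- function(genome) {
  g <- genome$genes
  L <- nchar(genome$letters)
  ok <- g$promoter_first < g$tss & g$tss < g$terminator & g$terminator < L &
    (g$stop_codon - g$start_codon) %% 3L == 0L &
    g$stop_codon < g$mrna_len & g$rbs_last <= g$start_codon
  if (!all(ok)) stop("malformed synthetic genome annotations", call. = FALSE)
  mrna <- substr(rep(genome$letters, nrow(g)), g$tss + 1L, g$tss + g$mrna_len)
  starts <- substr(mrna, g$start_codon + 1L, g$start_codon + 3L)
  stops <- substr(mrna, g$stop_codon + 1L, g$stop_codon + 3L)
  if (!all(starts == "ATG") || !all(stops %in% STOP_CODONS))
    stop("misplaced start/stop codons in synthetic genome", call. = FALSE)
  invisible(genome)
}

#' @export
print.ps_genome <- function(x, ...) {
  cat("<ps_genome> ", nrow(x$genes), " genes, ", nchar(x$letters),
      " nt, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

transcript_letters <- function(genome, i) {
  g <- genome$genes[i, ]
  substr(genome$letters, g$tss + 1L, g$tss + g$mrna_len)
}

#' Write genome sequences as FASTA
#'
#' @param genome A `ps_genome`.
#' @param path Output FASTA file; the genome record is named `genome`, and
#'   each transcript `mRNA_<gene>`.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- c(genome = genome$letters)
  for (i in seq_len(nrow(genome$genes)))
    seqs[paste0("mRNA_", genome$genes$gene[i])] <- transcript_letters(genome, i)
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
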