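# Synthetic genomes with planted sigma-style promoters (-35 box, spacer,
# -10 box, per-position noise) plus matching annotation tables, so every
# pipeline stage is testable without downloads.

#' Specify a synthetic genome with planted promoters
#'
#' Each planted promoter is a mutated -35 box, a uniform-random spacer of
#' sampled length, and a mutated -10 box, embedded in an i.i.d. background
#' of the given GC content. The promoter element starts at the annotated
#' absolute position, so the extracted window covers the element plus
#' downstream background — the same anchoring convention
#' [extract_promoters()] uses.
#'
#' @param genome_length Genome length in nt (default 50000).
#' @param n_promoters Number of planted promoters (default 20).
#' @param minus35,minus10 Consensus boxes (defaults `TTGACA` / `TATAAT`,
#'   the canonical sigma-70 hexamers).
#' @param spacer_range Inclusive spacer-length interval (default 15-19 nt,
#'   the canonical -35/-10 geometry).
#' @param mutation_rate Per-position substitution probability applied to
#'   both boxes, in `[0, 1)` (default 0.05).
#' @param gc_background Background GC fraction (default 0.43, approximately
#'   the B. subtilis genome composition).
#' @param window_length Promoter window length (default 80 nt).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(genome_length = 50000, n_promoters = 20,
                       minus35 = "TTGACA", minus10 = "TATAAT",
                       spacer_range = c(15, 19), mutation_rate = 0.05,
                       gc_background = 0.43, window_length = 80, seed = 0) {
  stopifnot(
    genome_length >= 1, n_promoters >= 1,
    nchar(minus35) >= 1, nchar(minus10) >= 1,
    length(spacer_range) == 2, spacer_range[1] <= spacer_range[2],
    spacer_range[1] >= 0,
    mutation_rate >= 0, mutation_rate < 1,
    gc_background > 0, gc_background < 1,
    window_length >= nchar(minus35) + spacer_range[2] + nchar(minus10)
  )
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_promoters = as.integer(n_promoters),
      minus35 = toupper(minus35), minus10 = toupper(minus10),
      spacer_range = as.integer(spacer_range),
      mutation_rate = mutation_rate, gc_background = gc_background,
      window_length = as.integer(window_length), seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

.random_dna <- function(n, gc) {
  if (n == 0L) {
    return(character(0))
  }
  sample(
    .dna_bases, n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
}

.mutate_seq <- function(chars, rate) {
  if (rate <= 0) {
    return(chars)
  }
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(.dna_bases, chars[i]), 1L)
  }
  chars
}

#' Generate a synthetic genome with planted promoters
#'
#' The genome is partitioned into `n_promoters` equal blocks and one
#' promoter window is placed at a random offset inside each block, so
#' planted windows never overlap. Returns the genome, an annotation table
#' in exactly the dialect [read_annotation()] parses (1-based absolute
#' positions; the binding sequence is the post-mutation planted element),
#' and the ground-truth windows under the extraction anchoring convention.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_genome`: a list with `genome` (a
#'   [genome()]), `records` (annotation tibble), `truth` (tibble of true
#'   windows: `operon`, `start`, `end`, `strand`, `seq`), `elements`
#'   (0-based half-open ranges of the planted boxes+spacer) and the `spec`.
#' @examples
#' sim <- generate_genome(synth_spec(genome_length = 5000, n_promoters = 3))
#' sim$records
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- spec$genome_length
  n <- spec$n_promoters
  W <- spec$window_length
  block <- L %/% n
  if (block < W + 10L) {
    max_n <- max(0L, L %/% (W + 10L))
    abort(
      sprintf(
        "genome too small to place %d non-overlapping %d-nt windows (maximum feasible: %d)",
        n, W, max_n
      ),
      class = "bacsvm_capacity_error"
    )
  }

  out <- withr::with_seed(spec$seed, {
    bg <- .random_dna(L, spec$gc_background)
    starts <- integer(n)
    elements <- character(n)
    for (i in seq_len(n)) {
      offset <- sample.int(block - W + 1L, 1L) - 1L
      p0 <- (i - 1L) * block + offset
      spacer_len <- sample(seq(spec$spacer_range[1], spec$spacer_range[2]), 1L)
      element <- c(
        .mutate_seq(strsplit(spec$minus35, "")[[1]], spec$mutation_rate),
        .random_dna(spacer_len, 0.5),
        .mutate_seq(strsplit(spec$minus10, "")[[1]], spec$mutation_rate)
      )
      bg[(p0 + 1L):(p0 + length(element))] <- element
      starts[i] <- p0
      elements[i] <- paste(element, collapse = "")
    }
    list(seq = paste(bg, collapse = ""), starts = starts, elements = elements)
  })

  g <- genome(out$seq, id = "synthetic_genome",
    desc = sprintf("synthetic genome, %d planted promoters, seed %d", n, spec$seed)
  )
  records <- tibble(
    operon = sprintf("synP%03d", seq_len(n)),
    sigma = "SigA",
    regulated_gene = sprintf("gene%03d", seq_len(n)),
    absolute_position = out$starts + 1L,
    binding_sequence = out$elements,
    location = "synthetic",
    evidence = "synthetic"
  )
  truth <- tibble(
    operon = records$operon,
    start = out$starts,
    end = out$starts + W,
    strand = "+",
    seq = vapply(
      out$starts, function(s) genome_slice(g, s, s + W), character(1)
    )
  )
  structure(
    list(
      genome = g, records = records, truth = truth,
      elements = tibble(
        start = out$starts,
        end = out$starts + nchar(out$elements)
      ),
      spec = spec
    ),
    class = "synth_genome"
  )
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf(
    "<synth_genome> %d nt, %d planted promoter(s) (mutation rate %g, seed %d)\n",
    x$genome$length, nrow(x$records), x$spec$mutation_rate, x$spec$seed
  ))
  invisible(x)
}

#' Generate a ready-to-search labeled benchmark
#'
#' Runs the full data-preparation path on a synthetic genome: plants
#' promoters with [generate_genome()], recovers them with
#' [extract_promoters()], samples negatives with [sample_negatives()] and
#' encodes everything with [build_dataset()]. With `n_negatives = 0` the
#' result is one-class compatible.
#'
#' @param spec A [synth_spec()].
#' @param n_negatives Number of negatives (default: one per positive).
#' @param seed Seed for the negative sampling (default `spec$seed + 1` so
#'   it is decoupled from genome generation but still fully determined).
#' @param encoding A [feature_encoding()].
#' @param strategy Negative-sampling strategy, see [sample_negatives()].
#' @return A `promoter_dataset`.
#' @export
generate_benchmark <- function(spec, n_negatives = spec$n_promoters,
                               seed = spec$seed + 1L,
                               encoding = feature_encoding("onehot"),
                               strategy = "random_window") {
  sim <- generate_genome(spec)
  report <- extract_promoters(
    sim$genome, sim$records,
    window_length = spec$window_length
  )
  if (nrow(report$windows) == 0L) {
    abort("no promoters recovered from the synthetic genome",
      class = "bacsvm_argument_error"
    )
  }
  negatives <- sample_negatives(
    sim$genome, report, n_negatives,
    seed = seed, strategy = strategy
  )
  build_dataset(report, negatives, encoding)
}

#' Write a synthetic genome bundle to disk
#'
#' Writes `genome.fasta`, `annotations.tsv` (the dialect
#' [read_annotation()] reads) and `truth.bed` (0-based half-open BED of the
#' true windows) into a directory.
#'
#' @param sim A `synth_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synth <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.bed")
  )
  write_fasta(
    tibble(id = sim$genome$id, desc = sim$genome$desc, seq = sim$genome$seq),
    paths[["genome"]]
  )
  readr::write_tsv(sim$records, paths[["annotations"]], progress = FALSE)
  bed <- tibble(
    chrom = sim$genome$id, start = sim$truth$start, end = sim$truth$end,
    name = sim$truth$operon, score = 0L, strand = sim$truth$strand
  )
  readr::write_tsv(bed, paths[["truth"]], col_names = FALSE, progress = FALSE)
  invisible(paths)
}
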