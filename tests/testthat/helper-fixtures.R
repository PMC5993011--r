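# Shared fixtures and independent oracles, all built in code.

# 200-nt toy genome with TTGACA planted at 1-based position 41.
toy_genome <- function() {
  genome(paste0(strrep("A", 40), "TTGACA", strrep("C", 154)), id = "toy")
}

toy_record <- function(position = 41L, binding = "TTGACA", operon = "op1") {
  tibble::tibble(
    operon = operon, sigma = "SigA", regulated_gene = NA_character_,
    absolute_position = position, binding_sequence = binding,
    location = NA_character_, evidence = NA_character_
  )
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent nearest-centroid classifier, cross-validated with its own
# fold logic. Kept free of any SVM machinery so it can serve as an oracle.
nearest_centroid_cv <- function(x, labels, folds = 5, seed = 1) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- fold == f
    cents <- vapply(
      unique(labels[tr]),
      function(cl) colMeans(x[tr & labels == cl, , drop = FALSE]),
      numeric(ncol(x))
    )
    d <- vapply(
      seq_len(ncol(cents)),
      function(j) rowSums((x[te, , drop = FALSE] - matrix(
        cents[, j], sum(te), ncol(x),
        byrow = TRUE
      ))^2),
      numeric(sum(te))
    )
    pred <- colnames(cents)[apply(matrix(d, ncol = ncol(cents)), 1, which.min)]
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}

# Dinucleotide multiset of a sequence, as a sorted character vector.
dinuc_multiset <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) {
    return(character(0))
  }
  sort(paste0(ch[-length(ch)], ch[-1]))
}

# The reduced benchmark grid used in the classifier sanity checks:
# C_SVC x {LINEAR, RBF} x 3 costs x 3 gammas, subsets of the full sweep.
reduced_benchmark_spec <- function() {
  grid_spec(
    svm_types = "C_SVC", kernels = c("LINEAR", "RBF"),
    c_min = 0.0625, c_max = 16, c_factor = 16,
    g_min = 2.44140625e-4, g_max = 0.0625, g_factor = 16
  )
}

# Study conditions of the separable classifier benchmark: 200 positives /
# 200 negatives at mutation rate 0.02, one-hot encoding.
benchmark_dataset <- function(seed = 2024) {
  generate_benchmark(
    synth_spec(
      genome_length = 100000, n_promoters = 200,
      mutation_rate = 0.02, seed = seed
    ),
    n_negatives = 200
  )
}
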