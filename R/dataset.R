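# Data preparation: negative-example construction and sequence-to-feature
# encoding producing a labeled promoter / non-promoter dataset.

.dna_bases <- c("A", "C", "G", "T")

#' Describe a sequence feature encoding
#'
#' Two encodings are provided. `"onehot"` is position-aware: each position
#' contributes four binary channels in the fixed order A, C, G, T, giving
#' dimension `4 * window_length`; it suits the conserved spacing of the
#' -35/-10 promoter boxes. `"kmer"` is composition-based: frequencies of
#' the `4^k` overlapping k-mers (lexicographic column order), each row
#' normalised by `L - k + 1` so it sums to 1.
#'
#' @param scheme `"onehot"` or `"kmer"`.
#' @param k k-mer length (kmer scheme only; default 3).
#' @param window_length Sequence length the encoding applies to; may be
#'   left `NULL` and inferred at encode time.
#' @return An object of class `feature_encoding`.
#' @export
feature_encoding <- function(scheme = c("onehot", "kmer"), k = 3, window_length = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "kmer" && (k < 1 || k != round(k))) {
    abort("k must be a positive integer", class = "bacsvm_argument_error")
  }
  structure(
    list(
      scheme = scheme,
      k = if (scheme == "kmer") as.integer(k) else NA_integer_,
      window_length = if (!is.null(window_length)) as.integer(window_length) else NA_integer_,
      dimension = if (scheme == "kmer") {
        4L^as.integer(k)
      } else if (!is.null(window_length)) {
        4L * as.integer(window_length)
      } else {
        NA_integer_
      }
    ),
    class = "feature_encoding"
  )
}

#' @export
print.feature_encoding <- function(x, ...) {
  cat(sprintf(
    "<feature_encoding> %s%s (window %s, dimension %s)\n", x$scheme,
    if (x$scheme == "kmer") paste0(" k=", x$k) else "",
    ifelse(is.na(x$window_length), "?", x$window_length),
    ifelse(is.na(x$dimension), "?", x$dimension)
  ))
  invisible(x)
}

.seq_chr <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("seq" %in% names(x))
    out <- x$seq
    names(out) <- if ("id" %in% names(x)) x$id else NULL
    out
  } else if (inherits(x, "extraction_report")) {
    out <- x$windows$seq
    names(out) <- x$windows$operon
    out
  } else {
    out <- as.character(x)
    names(out) <- names(x)
    out
  }
}

#' Encode DNA sequences into a numeric feature matrix
#'
#' @param sequences Character vector of equal-length DNA strings, or a
#'   tibble with a `seq` column, or an `extraction_report`.
#' @param encoding A [feature_encoding()]; default one-hot.
#' @return A numeric matrix, one row per sequence. One-hot rows contain
#'   exactly `window_length` ones; k-mer rows sum to 1.
#' @examples
#' encode_sequences("AAAA", feature_encoding("kmer", k = 2))
#' @export
encode_sequences <- function(sequences, encoding = feature_encoding("onehot")) {
  stopifnot(inherits(encoding, "feature_encoding"))
  seqs <- toupper(.seq_chr(sequences))
  if (length(seqs) == 0L) {
    abort("no sequences to encode", class = "bacsvm_argument_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("sequences must all have the same length", class = "bacsvm_argument_error")
  }
  L <- lens[1]
  if (!is.na(encoding$window_length) && L != encoding$window_length) {
    abort(
      sprintf(
        "sequences are %d nt but the encoding expects %d nt", L, encoding$window_length
      ),
      class = "bacsvm_contract_error"
    )
  }

  if (encoding$scheme == "onehot") {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      nm <- names(seqs)[bad][1] %||% as.character(which(bad)[1])
      abort(
        sprintf("one-hot encoding requires the A,C,G,T alphabet; sequence '%s' contains other characters", nm),
        class = "bacsvm_encoding_error"
      )
    }
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs), byrow = TRUE)
    x <- matrix(0, nrow = length(seqs), ncol = 4L * L)
    ch_idx <- match(chars, .dna_bases)
    pos <- col(chars)
    x[cbind(as.vector(row(chars)), 4L * (as.vector(pos) - 1L) + as.vector(ch_idx))] <- 1
    colnames(x) <- paste0("p", rep(seq_len(L), each = 4L), "_", rep(.dna_bases, L))
  } else {
    k <- encoding$k
    if (L < k) {
      abort("sequences shorter than k", class = "bacsvm_argument_error")
    }
    counts <- oligonucleotideFrequency(DNAStringSet(seqs), width = k)
    x <- counts / (L - k + 1)
    x <- matrix(as.numeric(x), nrow = nrow(counts), dimnames = dimnames(counts))
  }
  rownames(x) <- names(seqs)
  x
}

# Altschul-Erickson dinucleotide shuffle: permutes a sequence while
# preserving its exact dinucleotide multiset. Draws from the current RNG
# stream (caller seeds).
.dinuc_shuffle <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 3L || length(unique(ch)) == 1L) {
    return(s)
  }
  verts <- unique(ch)
  sink <- ch[n]
  edges <- split(ch[-1], factor(ch[-n], levels = verts))

  # choose a random "last out-edge" for every non-sink vertex such that the
  # chosen edges form paths leading to the sink (rejection sampling; the
  # alphabet has at most 4 vertices so acceptance is quick)
  nonsink <- setdiff(verts[lengths(edges) > 0L], sink)
  repeat {
    last <- vapply(nonsink, function(v) {
      e <- edges[[v]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    ok <- all(vapply(nonsink, function(v) {
      seen <- character(0)
      while (v != sink) {
        if (v %in% seen || !(v %in% nonsink)) {
          return(FALSE)
        }
        seen <- c(seen, v)
        v <- last[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) break
  }

  arranged <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (is.null(e) || length(e) == 0L) {
      return(character(0))
    }
    if (v %in% nonsink) {
      idx <- which(e == last[[v]])[1]
      rest <- e[-idx]
      c(if (length(rest)) rest[sample.int(length(rest))], e[idx])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(arranged) <- verts
  used <- stats::setNames(rep(0L, length(verts)), verts)

  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- arranged[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Sample non-promoter example sequences
#'
#' Two constructions are offered. `"random_window"` draws windows of the
#' positives' length uniformly from the genome, rejecting any draw whose
#' coordinates overlap a positive window (and any window containing `N`),
#' so negatives are genuine non-promoter genomic background.
#' `"dinucleotide_shuffle"` permutes the positive sequences themselves
#' while exactly preserving each one's dinucleotide multiset, giving
#' composition-matched negatives. Both are deterministic for a fixed seed.
#'
#' @param genome A [genome()] object (required for `random_window`).
#' @param positives An `extraction_report`, or a tibble of windows with
#'   `start`, `end` and `seq` columns.
#' @param n Number of negatives to draw (`n = 0` returns an empty tibble).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param strategy `"random_window"` (default) or `"dinucleotide_shuffle"`.
#' @return A tibble with columns `id` and `seq`, `n` rows.
#' @export
sample_negatives <- function(genome, positives, n, seed = 0,
                             strategy = c("random_window", "dinucleotide_shuffle")) {
  strategy <- match.arg(strategy)
  if (inherits(positives, "extraction_report")) positives <- positives$windows
  stopifnot(is.data.frame(positives))
  if (n == 0L) {
    return(tibble(id = character(0), seq = character(0)))
  }
  if (nrow(positives) == 0L) {
    abort("no positive windows supplied", class = "bacsvm_argument_error")
  }
  W <- unique(nchar(positives$seq))
  stopifnot(length(W) == 1L)

  if (strategy == "dinucleotide_shuffle") {
    idx <- ((seq_len(n) - 1L) %% nrow(positives)) + 1L
    seqs <- withr::with_seed(seed, vapply(positives$seq[idx], .dinuc_shuffle, character(1)))
    return(tibble(id = sprintf("neg_shuffle_%04d", seq_len(n)), seq = unname(seqs)))
  }

  stopifnot(inherits(genome, "genome"))
  if (genome$length < W) {
    abort("genome shorter than the window length", class = "bacsvm_argument_error")
  }
  keep <- !is.na(positives$start %||% rep(NA_integer_, nrow(positives)))
  pos_start <- positives$start[keep]
  pos_end <- positives$end[keep]
  max_start <- genome$length - W
  res <- withr::with_seed(seed, {
    starts <- integer(0)
    seqs <- character(0)
    attempts <- 0L
    max_attempts <- max(1000L, 200L * n)
    while (length(starts) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      s <- sample.int(max_start + 1L, 1L) - 1L
      if (length(pos_start) && any(s < pos_end & (s + W) > pos_start)) next
      sq <- genome_slice(genome, s, s + W)
      if (grepl("N", sq, fixed = TRUE)) next
      starts <- c(starts, s)
      seqs <- c(seqs, sq)
    }
    list(starts = starts, seqs = seqs)
  })
  if (length(res$starts) < n) {
    abort(
      sprintf(
        "could not place %d non-overlapping negative windows (achievable: %d)",
        n, length(res$starts)
      ),
      class = "bacsvm_capacity_error"
    )
  }
  tibble(
    id = sprintf("neg_%d_%d", res$starts, res$starts + W),
    seq = res$seqs
  )
}

#' Build a labeled promoter / non-promoter dataset
#'
#' Rows are deterministic: positives first (in input order, labeled
#' `promoter`), then negatives (labeled `non_promoter`). Features are
#' computed with [encode_sequences()]. A dataset built without negatives is
#' flagged one-class compatible for the positives-only SVM formulation.
#'
#' @param positives An `extraction_report`, tibble with a `seq` column, or
#'   character vector of promoter window sequences (non-empty).
#' @param negatives Same forms, non-promoter sequences; may be empty.
#' @param encoding A [feature_encoding()].
#' @return An object of class `promoter_dataset`: a list with `info` (tibble
#'   `id`, `seq`, `label`), feature matrix `x`, the completed `encoding`,
#'   and `one_class` (`TRUE` when no negatives were given).
#' @export
build_dataset <- function(positives, negatives = character(0),
                          encoding = feature_encoding("onehot")) {
  pos <- .seq_chr(positives)
  neg <- .seq_chr(negatives)
  if (length(pos) == 0L) {
    abort("at least one positive sequence is required", class = "bacsvm_argument_error")
  }
  if (length(neg) > 0L && any(nchar(neg) != nchar(pos[1]))) {
    abort("negative sequences must match the positive window length",
      class = "bacsvm_argument_error"
    )
  }
  ids <- c(
    names(pos) %||% sprintf("pos_%04d", seq_along(pos)),
    names(neg) %||% sprintf("neg_%04d", seq_along(neg))
  )
  ids[!nzchar(ids)] <- sprintf("seq_%04d", which(!nzchar(ids)))
  ids <- make.unique(ids, sep = "_")
  seqs <- unname(c(pos, neg))
  label <- factor(
    c(rep("promoter", length(pos)), rep("non_promoter", length(neg))),
    levels = c("promoter", "non_promoter")
  )
  if (is.na(encoding$window_length)) {
    encoding <- feature_encoding(
      encoding$scheme,
      k = if (is.na(encoding$k)) 3 else encoding$k,
      window_length = nchar(seqs[1])
    )
  }
  x <- encode_sequences(stats::setNames(seqs, ids), encoding)
  structure(
    list(
      info = tibble(id = ids, seq = seqs, label = label),
      x = x,
      encoding = encoding,
      one_class = length(neg) == 0L
    ),
    class = "promoter_dataset"
  )
}

#' @export
print.promoter_dataset <- function(x, ...) {
  cat(sprintf(
    "<promoter_dataset> %d promoter + %d non-promoter sequences, %s features (%d dims)%s\n",
    sum(x$info$label == "promoter"), sum(x$info$label == "non_promoter"),
    x$encoding$scheme, ncol(x$x), if (x$one_class) " [one-class]" else ""
  ))
  invisible(x)
}

#' @describeIn build_dataset `tidy()` returns the per-sequence info tibble.
#' @param x A `promoter_dataset`.
#' @param ... Unused.
#' @method tidy promoter_dataset
#' @export
tidy.promoter_dataset <- function(x, ...) x$info

#' Write a dataset in the sparse LibSVM training-file format
#'
#' One example per line: the label (`+1` promoter, `-1` non-promoter)
#' followed by `index:value` pairs for the non-zero features, indices
#' 1-based ascending.
#'
#' @param dataset A `promoter_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(dataset, path) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  y <- ifelse(dataset$info$label == "promoter", "+1", "-1")
  lines <- vapply(seq_len(nrow(dataset$x)), function(i) {
    row <- dataset$x[i, ]
    nz <- which(row != 0)
    paste(y[i], paste(sprintf("%d:%.10g", nz, row[nz]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse LibSVM training file
#'
#' @param path Input path in `label index:value` format.
#' @param dimension Feature-space dimension; defaults to the largest index
#'   present.
#' @return A list with dense feature matrix `x` and label factor `y`
#'   (`promoter` for positive labels).
#' @export
read_svmlight <- function(path, dimension = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot open file: ", path), class = "bacsvm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  y <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  feats <- lapply(parts, function(p) {
    if (length(p) < 2L) {
      return(cbind(integer(0), numeric(0)))
    }
    kv <- do.call(rbind, strsplit(p[-1], ":", fixed = TRUE))
    cbind(as.integer(kv[, 1]), as.numeric(kv[, 2]))
  })
  dim_max <- max(c(1L, unlist(lapply(feats, function(f) f[, 1]))))
  dimension <- dimension %||% dim_max
  x <- matrix(0, nrow = length(lines), ncol = dimension)
  for (i in seq_along(feats)) {
    if (nrow(feats[[i]])) x[i, feats[[i]][, 1]] <- feats[[i]][, 2]
  }
  list(
    x = x,
    y = factor(
      ifelse(y > 0, "promoter", "non_promoter"),
      levels = c("promoter", "non_promoter")
    )
  )
}
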