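# Promoter window extraction: locate each annotated promoter by absolute
# position, fall back to exact sequence search, emit fixed-length windows.

#' Locate a promoter window at an annotated absolute position
#'
#' Anchoring convention: the 1-based `position` is the first base of the
#' window, so the window covers genomic positions `position ...
#' position + window_length - 1` (shifted by `anchor_offset` when the
#' annotation anchor differs). When the record carries a binding sequence,
#' the genome slice must contain it for the hit to count; otherwise the
#' position alone decides.
#'
#' @param genome A [genome()] object.
#' @param position 1-based absolute genomic position.
#' @param binding_sequence Optional DNA string the window must contain.
#' @param window_length Window length in nucleotides (default 80).
#' @param anchor_offset Signed shift applied to the anchor (default 0).
#' @return A one-row tibble with columns `found`, `reason`, `start`, `end`
#'   (0-based half-open), `strand`, `provenance` and `seq`. When the window
#'   cannot be placed, `found` is `FALSE` and `reason` is one of
#'   `"position_out_of_range"` or `"binding_mismatch"`.
#' @export
locate_by_position <- function(genome, position, binding_sequence = NULL,
                               window_length = 80, anchor_offset = 0) {
  stopifnot(inherits(genome, "genome"))
  if (is.na(position) || position < 1) {
    abort("position must be a 1-based coordinate >= 1", class = "bacsvm_argument_error")
  }
  miss <- function(reason) {
    tibble(
      found = FALSE, reason = reason, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, provenance = NA_character_, seq = NA_character_
    )
  }
  start <- as.integer(position - 1L + anchor_offset)
  end <- start + as.integer(window_length)
  if (start < 0L || position > genome$length ||
    (!genome$circular && end > genome$length)) {
    return(miss("position_out_of_range"))
  }
  seq <- genome_slice(genome, start, end)
  if (!is.null(binding_sequence) && !is.na(binding_sequence) &&
    !grepl(toupper(binding_sequence), seq, fixed = TRUE)) {
    return(miss("binding_mismatch"))
  }
  tibble(
    found = TRUE, reason = NA_character_, start = start, end = end,
    strand = "+", provenance = "position", seq = seq
  )
}

#' Find all exact occurrences of a binding sequence in a genome
#'
#' Reports every (possibly overlapping) exact match on the forward strand,
#' then every match of the reverse complement (reported as strand `-`),
#' each in ascending coordinate order.
#'
#' @inheritParams locate_by_position
#' @param query DNA string to search for (length >= 1).
#' @return A tibble with columns `start` (0-based position of the match on
#'   the forward genome string) and `strand` (`"+"` or `"-"`).
#' @export
locate_by_sequence <- function(genome, query) {
  stopifnot(inherits(genome, "genome"))
  if (is.null(query) || is.na(query) || !nzchar(query)) {
    abort("query sequence must be non-empty", class = "bacsvm_argument_error")
  }
  query <- toupper(query)
  subject <- DNAString(genome$seq)
  fwd <- Biostrings::start(matchPattern(DNAString(query), subject)) - 1L
  rev <- Biostrings::start(
    matchPattern(DNAString(reverse_complement(query)), subject)
  ) - 1L
  bind_rows(
    tibble(start = sort(fwd), strand = "+"),
    tibble(start = sort(rev), strand = "-")
  )
}

# Window placed so the located binding sequence starts the (strand-oriented)
# window: on +, [s, s+W); on -, [s+L-W, s+L) reverse-complemented, whose
# first bases read as the query.
.window_from_hit <- function(genome, hit_start, strand, query_len, window_length) {
  if (strand == "+") {
    start <- hit_start
  } else {
    start <- hit_start + query_len - as.integer(window_length)
  }
  end <- start + as.integer(window_length)
  if (start < 0L || (!genome$circular && end > genome$length)) {
    return(NULL)
  }
  seq <- genome_slice(genome, start, end)
  if (strand == "-") seq <- reverse_complement(seq)
  list(start = start, end = end, seq = seq)
}

#' Extract fixed-length promoter windows for a table of annotated promoters
#'
#' The core extraction step: each record is first looked up by its absolute
#' position ([locate_by_position()]); on a miss the binding sequence is
#' searched for exactly in both strands ([locate_by_sequence()]). The first
#' sequence-search hit — forward strand preferred, then lowest coordinate —
#' defines the window; records with several hits still yield one window but
#' are listed in the `ambiguous` table. Records with no usable hit are
#' listed in `misses` with a reason, and (by default) windows containing
#' `N` are dropped to `misses` with reason `"ambiguous_base"` because
#' downstream encodings assume a 4-letter alphabet.
#'
#' @inheritParams locate_by_position
#' @param records A tibble of promoter records as returned by
#'   [read_annotation()] (columns `operon`, `sigma`, `absolute_position`,
#'   `binding_sequence`, ...).
#' @param drop_n Drop windows containing `N`? Default `TRUE`.
#' @return An object of class `extraction_report` with tibble components
#'   `windows` (one row per extracted window: record fields plus `start`,
#'   `end`, `strand`, `provenance`, `seq`), `misses` (record fields plus
#'   `reason`) and `ambiguous` (record fields plus `n_hits`).
#'   `nrow(windows) + nrow(misses) == nrow(records)` always holds.
#' @examples
#' g <- genome(paste0(
#'   strrep("A", 40), "TTGACA", strrep("C", 154)
#' ))
#' rec <- tibble::tibble(
#'   operon = "op1", sigma = "SigA", regulated_gene = NA,
#'   absolute_position = 41L, binding_sequence = "TTGACA",
#'   location = NA, evidence = NA
#' )
#' extract_promoters(g, rec)
#' @export
extract_promoters <- function(genome, records, window_length = 80,
                              anchor_offset = 0, drop_n = TRUE) {
  stopifnot(inherits(genome, "genome"), is.data.frame(records))
  if (nrow(records) == 0L) {
    abort("no promoter records supplied", class = "bacsvm_argument_error")
  }
  rec_cols <- intersect(
    c("operon", "sigma", "regulated_gene", "absolute_position", "binding_sequence"),
    names(records)
  )

  one <- function(i) {
    rec <- records[i, ]
    pos <- rec[["absolute_position"]] %||% NA
    bind <- rec[["binding_sequence"]] %||% NA
    reason <- "no_locator"

    if (!is.na(pos)) {
      hit <- locate_by_position(genome, pos, bind, window_length, anchor_offset)
      if (hit$found) {
        return(list(window = hit, n_hits = NA_integer_))
      }
      reason <- hit$reason
    }
    if (!is.na(bind) && nzchar(bind)) {
      hits <- locate_by_sequence(genome, bind)
      # forward strand preferred, then lowest coordinate; skip hits whose
      # window would run off a linear genome
      hits <- hits[order(hits$strand != "+", hits$start), ]
      for (j in seq_len(nrow(hits))) {
        w <- .window_from_hit(
          genome, hits$start[j], hits$strand[j], nchar(bind), window_length
        )
        if (!is.null(w)) {
          win <- tibble(
            found = TRUE, reason = NA_character_, start = w$start, end = w$end,
            strand = hits$strand[j], provenance = "sequence_search", seq = w$seq
          )
          return(list(window = win, n_hits = nrow(hits)))
        }
      }
      reason <- if (nrow(hits) == 0L) "sequence_not_found" else "window_out_of_range"
    }
    list(window = NULL, n_hits = NA_integer_, reason = reason)
  }

  windows <- list()
  misses <- list()
  ambiguous <- list()
  for (i in seq_len(nrow(records))) {
    res <- one(i)
    rec <- records[i, rec_cols]
    if (is.null(res$window)) {
      misses[[length(misses) + 1L]] <- mutate(rec, reason = res$reason)
      next
    }
    w <- res$window
    if (drop_n && grepl("N", w$seq, fixed = TRUE)) {
      misses[[length(misses) + 1L]] <- mutate(rec, reason = "ambiguous_base")
      next
    }
    windows[[length(windows) + 1L]] <- dplyr::bind_cols(
      rec,
      w[, c("start", "end", "strand", "provenance", "seq")]
    )
    if (!is.na(res$n_hits) && res$n_hits > 1L) {
      ambiguous[[length(ambiguous) + 1L]] <- mutate(rec, n_hits = res$n_hits)
    }
  }

  empty_rec <- as_tibble(records[0, rec_cols])
  empty_win <- dplyr::bind_cols(empty_rec, tibble(
    start = integer(0), end = integer(0), strand = character(0),
    provenance = character(0), seq = character(0)
  ))
  structure(
    list(
      windows = if (length(windows)) bind_rows(windows) else empty_win,
      misses = if (length(misses)) bind_rows(misses) else mutate(empty_rec, reason = character(0)),
      ambiguous = if (length(ambiguous)) bind_rows(ambiguous) else mutate(empty_rec, n_hits = integer(0)),
      window_length = as.integer(window_length),
      anchor_offset = as.integer(anchor_offset),
      genome_id = genome$id
    ),
    class = "extraction_report"
  )
}

#' @export
print.extraction_report <- function(x, ...) {
  cat(sprintf(
    "<extraction_report> genome %s: %d window(s) of %d nt, %d miss(es), %d ambiguous\n",
    x$genome_id, nrow(x$windows), x$window_length, nrow(x$misses), nrow(x$ambiguous)
  ))
  invisible(x)
}

#' @describeIn extract_promoters `tidy()` returns the windows tibble.
#' @param x An `extraction_report`.
#' @param ... Unused.
#' @method tidy extraction_report
#' @export
tidy.extraction_report <- function(x, ...) x$windows

#' @describeIn extract_promoters `glance()` returns one-row run totals.
#' @method glance extraction_report
#' @export
glance.extraction_report <- function(x, ...) {
  tibble(
    n_records = nrow(x$windows) + nrow(x$misses),
    n_windows = nrow(x$windows),
    n_misses = nrow(x$misses),
    n_ambiguous = nrow(x$ambiguous),
    window_length = x$window_length
  )
}

#' Write extracted windows as FASTA
#'
#' @param report An `extraction_report`.
#' @param path Output FASTA path, or a directory when `by_sigma = TRUE`
#'   (one file per sigma factor, `<sigma>.fasta`, mirroring a
#'   per-sigma-factor deposit layout).
#' @param by_sigma Split output by sigma factor?
#' @return The written path(s), invisibly.
#' @export
write_windows_fasta <- function(report, path, by_sigma = FALSE) {
  stopifnot(inherits(report, "extraction_report"))
  w <- report$windows
  if (nrow(w) == 0L) {
    abort("no windows to write", class = "bacsvm_argument_error")
  }
  recs <- tibble(
    id = sprintf("%s|%s|%d|%s", w$operon, w$sigma, w$start + 1L, w$strand),
    seq = w$seq
  )
  if (!by_sigma) {
    return(write_fasta(recs, path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (sig in unique(w$sigma)) {
    write_fasta(recs[w$sigma == sig, ], file.path(path, paste0(sig, ".fasta")))
  }
  invisible(file.path(path, paste0(unique(w$sigma), ".fasta")))
}

#' Write a per-record extraction report as CSV
#'
#' One row per input record with its status (`window`, `miss`), coordinates
#' and miss reason, sorted in input order within status.
#'
#' @inheritParams write_windows_fasta
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "extraction_report"))
  w <- mutate(report$windows,
    status = "window",
    reason = NA_character_
  )
  m <- mutate(report$misses,
    status = "miss", start = NA_integer_, end = NA_integer_,
    strand = NA_character_, provenance = NA_character_, seq = NA_character_
  )
  cols <- c(
    "status", "operon", "sigma", "absolute_position", "binding_sequence",
    "start", "end", "strand", "provenance", "reason", "seq"
  )
  out <- bind_rows(w, m)
  readr::write_csv(out[, intersect(cols, names(out))], path, progress = FALSE)
  invisible(path)
}
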