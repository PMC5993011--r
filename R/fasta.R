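# Sequence I/O: FASTA reading/writing, genomes, strand arithmetic.
#
# Coordinate convention used throughout the package: annotation tables carry
# 1-based inclusive positions (the DBTBS convention); every internal
# coordinate is 0-based half-open [start, end). The conversion happens
# exactly once, at annotation-parse time.

.iupac_dna <- "ACGTMRWSYKVHDBN"

.validate_fasta_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, ">") & nzchar(lines))
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0L || (length(body) > 0L && body[1] < headers[1])) {
    abort(
      paste0("not a FASTA file (no '>' header before sequence data): ", path),
      class = "bacsvm_format_error"
    )
  }
  pattern <- sprintf("[^%s%s]", .iupac_dna, tolower(.iupac_dna))
  bad <- body[grepl(pattern, lines[body])]
  if (length(bad) > 0L) {
    ch <- regmatches(lines[bad[1]], regexpr(pattern, lines[bad[1]]))
    abort(
      sprintf(
        "invalid character '%s' on line %d of %s (not an IUPAC DNA code)",
        ch, bad[1], path
      ),
      class = "bacsvm_format_error"
    )
  }
  invisible(lines)
}

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased on load and wrapped lines are concatenated, so
#' every residue string handed to downstream functions is a single uppercase
#' string. The first whitespace-delimited token of each header is the record
#' id; the remainder (if any) is kept as `desc`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc` and `seq`, one row per record.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "acg", "t"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot open FASTA file: ", path), class = "bacsvm_io_error")
  }
  .validate_fasta_text(path)
  dss <- readDNAStringSet(path)
  full <- names(dss) %||% character(0)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  tibble(id = id, desc = desc, seq = toupper(as.character(dss, use.names = FALSE)))
}

#' Write sequence records to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq` (optionally `desc`), or a
#'   named character vector of sequences.
#' @param path Output file path.
#' @param line_width Sequence line width on output (default 70).
#' @return `path`, invisibly. `read_fasta(write_fasta(x, path))` reproduces
#'   ids and residues exactly.
#' @export
write_fasta <- function(x, path, line_width = 70) {
  if (is.character(x)) {
    x <- tibble(id = names(x) %||% paste0("seq", seq_along(x)), seq = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (nrow(x) == 0L) {
    abort("no records to write", class = "bacsvm_argument_error")
  }
  if (line_width < 1) {
    abort("line_width must be a positive integer", class = "bacsvm_argument_error")
  }
  dss <- DNAStringSet(toupper(x$seq))
  nm <- x$id
  if ("desc" %in% names(x)) {
    nm <- ifelse(nzchar(x$desc %||% ""), paste(x$id, x$desc), x$id)
  }
  names(dss) <- nm
  tryCatch(
    writeXStringSet(dss, filepath = path, width = line_width),
    error = function(e) {
      abort(paste0("cannot write FASTA file: ", path), class = "bacsvm_io_error")
    }
  )
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorised; length and alphabet are preserved and `N` maps to `N`.
#' Applying it twice returns the input.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N` (IUPAC
#'   ambiguity codes are accepted and complemented by the usual rules).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("TTGACA") # "TGTCAA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl(sprintf("[^%s]", .iupac_dna), toupper(seq))
  if (any(bad)) {
    ch <- regmatches(
      toupper(seq[bad][1]),
      regexpr(sprintf("[^%s]", .iupac_dna), toupper(seq[bad][1]))
    )
    abort(
      sprintf("invalid character '%s' in DNA string", ch),
      class = "bacsvm_format_error"
    )
  }
  as.character(reverseComplement(DNAStringSet(toupper(seq))), use.names = FALSE)
}

#' Construct a genome object
#'
#' A genome is a single named DNA sequence with its coordinate conventions
#' attached. Residues outside `A,C,G,T,N` (IUPAC ambiguity codes) are
#' converted to `N` with a warning, since downstream encodings use a
#' 4-letter alphabet and `N`-containing windows are filtered explicitly.
#'
#' @param seq A single DNA string.
#' @param id Sequence label.
#' @param desc Free-text description.
#' @param circular Treat the genome as circular? When `TRUE`, windows may
#'   span the origin. Defaults to `FALSE`: although many bacterial
#'   chromosomes are circular, origin-spanning promoter windows are not
#'   needed for annotation-driven extraction.
#' @return An object of class `genome`.
#' @export
genome <- function(seq, id = "genome", desc = "", circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl(sprintf("[^%s]", .iupac_dna), seq)) {
    ch <- regmatches(seq, regexpr(sprintf("[^%s]", .iupac_dna), seq))
    abort(
      sprintf("invalid character '%s' in genome sequence", ch),
      class = "bacsvm_format_error"
    )
  }
  if (grepl("[^ACGTN]", seq)) {
    warn("ambiguity codes other than N present; converted to N")
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  structure(
    list(id = id, desc = desc, seq = seq, length = nchar(seq), circular = circular),
    class = "genome"
  )
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param id Record id to use when the file holds several records; by
#'   default the first record is taken (with a warning when others exist),
#'   matching the single-chromosome case.
#' @param circular Passed to [genome()].
#' @return A `genome` object.
#' @export
read_genome <- function(path, id = NULL, circular = FALSE) {
  recs <- read_fasta(path)
  if (nrow(recs) == 0L) {
    abort(paste0("no sequences in FASTA file: ", path), class = "bacsvm_format_error")
  }
  if (!is.null(id)) {
    recs <- recs[recs$id == id, ]
    if (nrow(recs) == 0L) {
      abort(sprintf("record '%s' not found in %s", id, path), class = "bacsvm_argument_error")
    }
  } else if (nrow(recs) > 1L) {
    warn(sprintf(
      "%d records in %s; using the first ('%s')", nrow(recs), path, recs$id[1]
    ))
  }
  genome(recs$seq[1], id = recs$id[1], desc = recs$desc[1], circular = circular)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf(
    "<genome> %s: %s nt (%s)\n", x$id, format(x$length, big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

# Slice [start, end) in 0-based half-open coordinates; wraps the origin for
# circular genomes. Bounds must be validated by the caller for linear ones.
genome_slice <- function(g, start, end) {
  stopifnot(inherits(g, "genome"), end >= start)
  if (end <= g$length) {
    return(substr(g$seq, start + 1L, end))
  }
  if (!g$circular) {
    abort("slice beyond the end of a linear genome", class = "bacsvm_argument_error")
  }
  paste0(
    substr(g$seq, start + 1L, g$length),
    substr(g$seq, 1L, end - g$length)
  )
}
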