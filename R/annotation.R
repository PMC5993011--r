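# Annotation-table parsing: DBTBS-style promoter tables (operon, sigma
# factor, absolute position, binding sequence, location, evidence).

.ann_aliases <- list(
  operon = c("operon"),
  sigma = c("sigma", "sigma_factor", "factor"),
  regulated_gene = c("regulated_gene", "gene"),
  absolute_position = c("absolute_position", "position", "genome_position"),
  binding_sequence = c("binding_sequence", "sequence", "link_sequence"),
  location = c("location"),
  evidence = c("evidence", "experimental_evidence")
)

.norm_colname <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

#' Read a promoter annotation table
#'
#' Parses a delimited table of annotated promoters with (at least) an operon
#' column, a sigma-factor column, and one or both of an absolute-position
#' and a binding-sequence column. Column names are matched
#' case-insensitively against common aliases (`position`,
#' `absolute_position`, `sequence`, `link_sequence`, ...). The delimiter is
#' sniffed from the header (tab, else comma) unless given.
#'
#' Positions in the file are 1-based inclusive; they are kept 1-based in the
#' returned table (`absolute_position`) and converted to internal 0-based
#' half-open coordinates only inside the extraction step. Rows that carry
#' neither a position nor a binding sequence are collected in the
#' `"problems"` attribute (with a warning) rather than aborting the parse.
#'
#' @param path Path to a TSV or CSV annotation table with a header row.
#' @param delim Field delimiter; `NULL` (default) sniffs `\t` vs `,`.
#' @return A tibble with columns `operon`, `sigma`, `regulated_gene`,
#'   `absolute_position` (integer, `NA` when absent), `binding_sequence`
#'   (uppercase, `NA` when absent), `location` and `evidence`. Skipped rows
#'   are in `attr(x, "problems")`.
#' @export
read_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot open annotation table: ", path), class = "bacsvm_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- .norm_colname(names(raw))

  pick <- function(field) {
    hit <- intersect(.ann_aliases[[field]], names(raw))
    if (length(hit) > 0L) raw[[hit[1]]] else rep(NA_character_, nrow(raw))
  }
  have <- function(field) any(.ann_aliases[[field]] %in% names(raw))

  missing_cols <- c(
    if (!have("operon")) "operon",
    if (!have("sigma")) "sigma",
    if (!have("absolute_position") && !have("binding_sequence")) {
      "absolute_position or binding_sequence"
    }
  )
  if (length(missing_cols) > 0L) {
    abort(
      paste0(
        "annotation table is missing mandatory column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "bacsvm_format_error"
    )
  }

  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  out <- tibble(
    operon = blank_to_na(pick("operon")),
    sigma = blank_to_na(pick("sigma")),
    regulated_gene = blank_to_na(pick("regulated_gene")),
    absolute_position = suppressWarnings(as.integer(blank_to_na(pick("absolute_position")))),
    binding_sequence = toupper(blank_to_na(pick("binding_sequence"))),
    location = blank_to_na(pick("location")),
    evidence = blank_to_na(pick("evidence"))
  )

  bad_pos <- !is.na(out$absolute_position) & out$absolute_position < 1L
  if (any(bad_pos)) {
    abort("absolute_position must be >= 1 (1-based coordinates)",
      class = "bacsvm_format_error"
    )
  }
  no_locator <- is.na(out$absolute_position) & is.na(out$binding_sequence)
  problems <- out[no_locator, ]
  if (nrow(problems) > 0L) {
    warn(sprintf(
      "%d row(s) carry neither a position nor a binding sequence; skipped",
      nrow(problems)
    ))
  }
  out <- out[!no_locator, ]
  attr(out, "problems") <- problems
  out
}
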