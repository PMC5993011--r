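# Annotation parsing and the position-first / sequence-fallback extraction.

test_that("annotation tables parse with aliased columns and row-level problems", {
  tbl <- read_annotation(test_path("sigl_synthetic.tsv"))
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$sigma, rep("SigL", 6))
  expect_equal(tbl$operon[1], "acoABCL")
  expect_true(is.na(tbl$absolute_position[6])) # blank cell -> absent optional
  expect_equal(tbl$absolute_position[1], 1201L)

  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Operon,Sigma,Position,Sequence"), tf)
  expect_equal(nrow(read_annotation(tf)), 0) # header-only file

  writeLines(c(
    "Operon,Sigma,Position,Sequence",
    "opA,SigA,10,ACGT",
    "opB,SigA,,",
    "opC,SigA,,TTTT"
  ), tf)
  expect_warning(tbl2 <- read_annotation(tf), "neither a position nor a binding sequence")
  expect_equal(nrow(tbl2), 2)
  expect_equal(attr(tbl2, "problems")$operon, "opB")

  writeLines(c("operon,sigma", "opA,SigA"), tf)
  err <- expect_error(read_annotation(tf), class = "bacsvm_format_error")
  expect_match(conditionMessage(err), "absolute_position or binding_sequence")
  writeLines(c("position,sequence", "10,ACGT"), tf)
  err2 <- expect_error(read_annotation(tf), class = "bacsvm_format_error")
  expect_match(conditionMessage(err2), "operon")
})

test_that("locate_by_position anchors the window at the annotated base", {
  g <- toy_genome()
  hit <- locate_by_position(g, 41, "TTGACA", window_length = 80)
  expect_true(hit$found)
  expect_equal(hit$start, 40L)
  expect_equal(hit$end, 120L)
  expect_equal(hit$provenance, "position")
  expect_equal(substr(hit$seq, 1, 6), "TTGACA")
  expect_equal(nchar(hit$seq), 80)

  over <- locate_by_position(g, 190, NULL, window_length = 80)
  expect_false(over$found)
  expect_equal(over$reason, "position_out_of_range")

  mism <- locate_by_position(g, 41, "GGGGGG", window_length = 80)
  expect_false(mism$found)
  expect_equal(mism$reason, "binding_mismatch")

  shifted <- locate_by_position(g, 46, "TTGACA", window_length = 80, anchor_offset = -5)
  expect_equal(shifted$start, 40L)
})

test_that("locate_by_sequence finds exact hits on both strands in order", {
  g1 <- genome("AAATTGACAAAA")
  hits <- locate_by_sequence(g1, "TTGACA")
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+")

  g2 <- genome("AAATGTCAAAAA") # TGTCAA = revcomp(TTGACA) at 0-based 3
  hits2 <- locate_by_sequence(g2, "TTGACA")
  expect_equal(hits2$start, 3L)
  expect_equal(hits2$strand, "-")

  expect_equal(nrow(locate_by_sequence(g1, "GGGG")), 0)
  expect_error(locate_by_sequence(g1, ""), class = "bacsvm_argument_error")

  # overlapping occurrences are all reported, ascending
  g3 <- genome("AAAA")
  expect_equal(locate_by_sequence(g3, "AA")$start, c(0L, 1L, 2L))
})

test_that("minus-strand fallback windows read the query at their start", {
  withr::local_seed(5)
  bg <- random_dna_string(200)
  query <- "TTGACAGGTACC"
  insert <- reverse_complement(query)
  seq <- paste0(substr(bg, 1, 100), insert, substr(bg, 113, 200))
  g <- genome(seq)
  rec <- toy_record(position = NA_integer_, binding = query)
  rep <- extract_promoters(g, rec, window_length = 50)
  expect_equal(nrow(rep$windows), 1)
  expect_equal(rep$windows$strand, "-")
  expect_equal(substr(rep$windows$seq, 1, nchar(query)), query)
  # window is re-derivable from its coordinates
  expect_equal(
    reverse_complement(substr(seq, rep$windows$start + 1, rep$windows$end)),
    rep$windows$seq
  )
})

test_that("extraction prefers positions, falls back to search, reports misses", {
  sim <- generate_genome(synth_spec(
    genome_length = 10000, n_promoters = 10, mutation_rate = 0.05, seed = 3
  ))
  rep_pos <- extract_promoters(sim$genome, sim$records)
  expect_equal(nrow(rep_pos$windows), 10)
  expect_equal(nrow(rep_pos$misses), 0)
  expect_true(all(rep_pos$windows$provenance == "position"))
  expect_equal(rep_pos$windows$seq, sim$truth$seq)

  blanked <- dplyr::mutate(sim$records, absolute_position = NA_integer_)
  rep_seq <- extract_promoters(sim$genome, blanked)
  expect_true(all(rep_seq$windows$provenance == "sequence_search"))
  expect_equal(rep_seq$windows$seq, rep_pos$windows$seq)

  bad <- toy_record(position = NA_integer_, binding = "GGGGGGGGGGGG", operon = "ghost")
  rep_bad <- extract_promoters(sim$genome, dplyr::bind_rows(sim$records, bad))
  expect_equal(nrow(rep_bad$windows), 10)
  expect_equal(nrow(rep_bad$misses), 1)
  expect_equal(rep_bad$misses$reason, "sequence_not_found")
  expect_equal(
    nrow(rep_bad$windows) + nrow(rep_bad$misses),
    nrow(sim$records) + 1
  )
  g <- glance(rep_bad)
  expect_equal(g$n_records, g$n_windows + g$n_misses)
})

test_that("ambiguous records yield one window and are surfaced", {
  g <- genome(paste0(
    strrep("C", 30), "TTGACAAT", strrep("C", 100), "TTGACAAT", strrep("C", 100)
  ))
  rec <- toy_record(position = NA_integer_, binding = "TTGACAAT")
  rep <- extract_promoters(g, rec, window_length = 40)
  expect_equal(nrow(rep$windows), 1)
  expect_equal(rep$windows$start, 30L) # lowest forward coordinate wins
  expect_equal(nrow(rep$ambiguous), 1)
  expect_equal(rep$ambiguous$n_hits, 2L)
})

test_that("windows containing N are dropped unless requested otherwise", {
  g <- genome(paste0(strrep("A", 10), "N", strrep("C", 60)))
  rec <- toy_record(position = 1L, binding = NULL)
  rep <- extract_promoters(g, rec, window_length = 40)
  expect_equal(nrow(rep$windows), 0)
  expect_equal(rep$misses$reason, "ambiguous_base")
  rep2 <- extract_promoters(g, rec, window_length = 40, drop_n = FALSE)
  expect_equal(nrow(rep2$windows), 1)
})

test_that("window FASTA and report CSV exports round-trip", {
  sim <- generate_genome(synth_spec(
    genome_length = 8000, n_promoters = 6, mutation_rate = 0, seed = 9
  ))
  rep <- extract_promoters(sim$genome, sim$records)
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_windows_fasta(rep, tf)
  back <- read_fasta(tf)
  expect_equal(back$seq, rep$windows$seq)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep, csv)
  parsed <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(parsed), 6)
  expect_true(all(parsed$status == "window"))
})
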