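make_toy_panel <- function() {
  panel_design(proteins = c("P1", "P2"),
               sample_ids = c("S1", "S2"),
               protein_tags = c("AAAAAAAA", "CCCCCCCC"),
               sample_tags = c("GGGGGGGG", "TTTTTTTT"))
}

test_that("read_layout validates segment geometry", {
  ly <- read_layout()
  expect_equal(ly$read_length, 39L)
  seg <- ly$segments
  expect_equal(seg$start[match(c("sample_tag", "ev_tag", "protein_tag", "umi"),
                               seg$name)], c(1L, 9L, 24L, 32L))
  expect_error(read_layout(segments = data.frame(
    name = c("sample_tag", "ev_tag", "protein_tag", "umi"),
    start = c(1L, 9L, 24L, 32L), length = c(8L, 14L, 8L, 8L))),
    "ev_tag must be 15")
  expect_error(read_layout(segments = data.frame(
    name = c("sample_tag", "ev_tag", "protein_tag", "umi"),
    start = c(1L, 8L, 24L, 32L), length = c(8L, 15L, 8L, 8L))),
    "overlap")
})

test_that("filter_quality keeps reads with mean Phred at or above threshold", {
  expect_true(filter_quality(c(19, 21)))            # mean 20, boundary kept
  expect_false(filter_quality(c(19, 20.9)))
  # character form: '5' encodes Phred 20, '!' encodes 0, 'I' encodes 40
  expect_identical(filter_quality(c("55", "!I", "!5", "II")),
                   c(TRUE, TRUE, FALSE, TRUE))
})

test_that("match_tag corrects unique 1-mismatch hits and refuses ambiguity", {
  dict <- c(AAAA = "x", CCCC = "y", AACC = "z")
  expect_identical(match_tag(c("AAAA", "CCCC"), dict), c("x", "y"))
  # GAAA is Hamming-1 from AAAA only
  expect_identical(match_tag("GAAA", dict, max_hamming = 1L), "x")
  expect_identical(match_tag("GAAA", dict, max_hamming = 0L), NA_character_)
  # CCCG is distance 1 from CCCC only -> corrects to y
  expect_identical(match_tag("CCCG", dict, max_hamming = 1L), "y")
  # ACCC is distance 1 from both CCCC and AACC -> ambiguous, NA
  expect_identical(match_tag("ACCC", dict, max_hamming = 1L), NA_character_)
  # ACAC: distance 2 from everything -> NA
  expect_identical(match_tag("ACAC", dict, max_hamming = 1L), NA_character_)
  # AAAC: distance 1 from AAAA and from AACC -> ambiguous, NA
  expect_identical(match_tag("AAAC", dict, max_hamming = 1L), NA_character_)
  expect_error(match_tag("AAA", dict), "length")
})

test_that("generated tag sets honour the minimum pairwise Hamming distance", {
  set.seed(1)
  tags <- make_tag_set(40L, 8L, 3L)
  expect_equal(length(tags), 40L)
  dmin <- min(vapply(seq_along(tags)[-1], function(i)
    min(vapply(seq_len(i - 1), function(j)
      hamming(tags[i], tags[j]), integer(1))), integer(1)))
  expect_gte(dmin, 3L)
})

test_that("build_matrix counts distinct UMIs and attributes rejections in order", {
  panel <- make_toy_panel()
  ev <- strrep("A", 15)
  fq <- tempfile(fileext = ".fastq")
  write_test_fastq(
    fq,
    sample_tag  = c("GGGGGGGG", "GGGGGGGG", "GGGGGGGG", "TTTTTTTT",
                    "ACGTACGT", "GGGGGGGG"),
    ev_tag      = rep(ev, 6),
    protein_tag = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "CCCCCCCC",
                    "AAAAAAAA", "AAAAAAAA"),
    umi         = c("ACGTACGT", "ACGTACGT", "TTTTACGT", "ACGTACGT",
                    "ACGTACGT", "ACGTACGT"),
    qual_char   = c("F", "F", "F", "F", "F", "!"))
  out <- build_matrix(fq, panel)
  # duplicate UMI collapses: S1 EV has 2 distinct UMIs for P1
  expect_equal(out$matrix$counts[paste0("S1:", ev), "P1"], 2)
  expect_equal(out$matrix$counts[paste0("S2:", ev), "P2"], 1)
  rpt <- out$report
  expect_equal(rpt$reads_in, 6L)
  expect_equal(rpt$rejected_low_quality, 1L)   # quality checked first
  expect_equal(rpt$rejected_sample_tag, 1L)
  expect_equal(rpt$rejected_protein_tag, 0L)
  expect_equal(rpt$accepted, 4L)
  expect_equal(rpt$reads_in,
               rpt$rejected_low_quality + rpt$rejected_sample_tag +
                 rpt$rejected_protein_tag + rpt$accepted)
})

test_that("zero accepted reads raises a typed condition carrying the report", {
  panel <- make_toy_panel()
  fq <- tempfile(fileext = ".fastq")
  write_test_fastq(fq, "ACACACAC", strrep("A", 15), "AAAAAAAA", "ACGTACGT")
  err <- tryCatch(build_matrix(fq, panel), pbaev_empty_decode = identity)
  expect_s3_class(err, "pbaev_empty_decode")
  expect_equal(err$report$reads_in, 1L)
  expect_equal(err$report$rejected_sample_tag, 1L)
})

test_that("noise-free decode reproduces the ground-truth matrix exactly", {
  d <- small_design(evs = 80, substitution_rate = 0,
                    pcr_duplication_mean = 1.6, seed = 17L)
  tr <- simulate_truth(d)
  panel <- panel_design(d$proteins, tr$samples$sample_id, seed = 3L)
  out <- emit_reads(tr, panel, dir = withr::local_tempdir())
  dec <- build_matrix(out$fastq, panel)
  truth_sev <- truth_matrix(tr)
  expect_setequal(rownames(dec$matrix$counts), rownames(truth_sev$counts))
  ord <- match(rownames(truth_sev$counts), rownames(dec$matrix$counts))
  expect_equal(as.matrix(dec$matrix$counts[ord, colnames(truth_sev$counts)]),
               as.matrix(truth_sev$counts))
})

test_that("1-mismatch correction recovers reads that exact matching drops", {
  d <- small_design(n_a = 2L, n_b = 2L, evs = 400,
                    substitution_rate = 0.01, seed = 19L)
  tr <- simulate_truth(d)
  panel <- panel_design(d$proteins, tr$samples$sample_id, seed = 3L)
  out <- emit_reads(tr, panel, dir = withr::local_tempdir())
  exact <- build_matrix(out$fastq, panel, max_hamming = 0L)
  corr <- build_matrix(out$fastq, panel, max_hamming = 1L)
  expect_gt(corr$report$accepted, exact$report$accepted)
  # corrected decode must not invent molecules beyond the emitted total
  expect_lte(corr$report$accepted, out$n_reads)
})

test_that("EV tags are scoped per sample and inputs are validated", {
  cnt <- data.frame(sample_id = c("S1", "S2"), ev_tag = "AAA",
                    protein = "P1", count = c(2L, 3L))
  sev <- single_ev_matrix(cnt)
  expect_equal(nrow(sev$counts), 2L)     # same tag, two samples, two EVs
  expect_error(single_ev_matrix(data.frame(sample_id = "S1", ev_tag = "A",
                                           protein = "P1", count = 0L)),
               "positive")
  expect_error(single_ev_matrix(cnt, proteins = "OTHER"), "universe")
})

test_that("write_sev / read_sev round-trips the matrix", {
  inc <- random_inc(30, rep(0.4, 6))
  sev <- sev_from_inc(inc, rep(c("S1", "S2", "S3"), each = 10))
  dir <- withr::local_tempdir()
  write_sev(sev, dir)
  back <- read_sev(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sev$counts))
  expect_equal(back$ev_info$sample_id, sev$ev_info$sample_id)
})
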