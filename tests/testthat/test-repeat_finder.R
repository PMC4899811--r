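test_that("perfect repeats score the closed form (l - p) * 2", {
  for (p in 1:6) {
    motif <- substr("ACGTAG", 1, p)
    for (copies in 3:8) {
      s <- strrep(motif, copies)
      l <- nchar(s)
      expect_identical(score_repeat_region(s, 0, l, p), (l - p) * 2L,
                       info = paste("p =", p, "copies =", copies))
    }
  }
  expect_identical(score_repeat_region(strrep("AATGG", 4), 0, 20, 5), 30L)
  expect_identical(score_repeat_region("AATGGAATGGAA", 0, 12, 5), 14L)
  expect_identical(score_repeat_region("AAAA", 0, 4, 1), 6L)
  expect_error(score_repeat_region("AAAA", 0, 4, 7), "period")
  expect_error(score_repeat_region("AAAA", 0, 1, 1), "exceed")
})

test_that("detection threshold is period + 7 bases for perfect repeats", {
  params <- repeat_params()
  for (p in 1:6) {
    motif <- substr("ACGTAG", 1, p)
    shortest <- p + ceiling(params$min_score / params$match_weight)  # p + 7
    too_short <- substr(strrep(motif, 20), 1, shortest - 1)
    long_enough <- substr(strrep(motif, 20), 1, shortest)
    expect_identical(nrow(find_tandem_repeats(too_short)), 0L, info = motif)
    h <- find_tandem_repeats(long_enough)
    expect_identical(nrow(h), 1L, info = motif)
    expect_identical(h$period, p)
    expect_identical(h$score, params$min_score)
  }
})

test_that("a planted pentamer is reported with exact coordinates", {
  # background crafted so no lag-5 pair at the boundaries matches by chance
  set.seed(101)
  repeat {
    bg <- rand_dna(100)
    s <- bg
    substr(s, 38, 57) <- strrep("AATGG", 4)
    h <- brute_force_repeats(s)
    if (nrow(h) == 1L && h$start == 37 && h$end == 57) break
  }
  got <- find_tandem_repeats(s)
  expect_identical(got, h)
  expect_identical(got$period, 5L)
  expect_identical(got$family, "AATGG")
  expect_identical(got$motif, "AATGG")
  expect_identical(got$copies, 4.0)
  expect_identical(got$score, 30L)
  expect_identical(got$percent_match, 100)
})

test_that("ties collapse toward the smaller period", {
  h <- find_tandem_repeats("ATATATATATAT")
  expect_identical(nrow(h), 1L)
  expect_identical(h$period, 2L)
  expect_identical(h$family, "AT")
  expect_identical(h$copies, 6.0)
  # short aperiodic string: nothing reaches score 14
  expect_identical(nrow(find_tandem_repeats("ACGTTGCA")), 0L)
  expect_identical(nrow(find_tandem_repeats("")), 0L)
})

test_that("hits are strand-symmetric with mirrored coordinates", {
  set.seed(21)
  for (i in 1:20) {
    s <- rand_with_repeat()
    fwd <- find_tandem_repeats(s)
    rev <- find_tandem_repeats(revcomp(s))
    expect_identical(nrow(fwd), nrow(rev), info = s)
    if (nrow(fwd) > 0) {
      n <- nchar(s)
      mirrored <- rev[order(n - rev$end), , drop = FALSE]
      expect_identical(fwd$start, n - mirrored$end, info = s)
      expect_identical(fwd$end, n - mirrored$start, info = s)
      expect_identical(fwd$family, mirrored$family, info = s)
      expect_identical(fwd$score, mirrored$score, info = s)
    }
  }
})

test_that("fast finder agrees with the brute-force oracle (quick check)", {
  set.seed(5)
  for (i in 1:60) {
    s <- rand_with_repeat()
    expect_identical(find_tandem_repeats(s), brute_force_repeats(s), info = s)
  }
})

test_that("TSV export is 1-based inclusive, BED stays 0-based half-open", {
  s <- paste0("ACGTCTGACTGA", strrep("AATGG", 4), "CTGAGTCA")
  h <- find_tandem_repeats(s, sequence_id = "ctg1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_tsv(h, tsv)
  write_hits_bed(h, bed)
  t <- read.delim(tsv)
  b <- read.delim(bed, header = FALSE)
  expect_identical(t$start, h$start + 1L)
  expect_identical(t$end, h$end)
  expect_identical(b$V2, h$start)
  expect_identical(b$V3, h$end)
})

test_that("invalid inputs are rejected", {
  expect_error(find_tandem_repeats("ACGTNACGT"), "strip Ns")
  expect_error(repeat_params(min_score = 0), "positive")
  expect_error(repeat_params(max_period = 7), "at most 6")
})
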