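test_that("Velvet IDs parse losslessly and reject malformed fields", {
  v <- parse_velvet_id("NODE_35_length_226_cov_17.079645")
  expect_identical(v$node_id, 35L)
  expect_identical(v$length, 226L)
  expect_equal(v$coverage, 17.079645)
  v0 <- parse_velvet_id("NODE_1_length_100_cov_0.0")
  expect_identical(v0$coverage, 0)
  expect_error(parse_velvet_id("NODE_x_length_10_cov_1"), "node field")
  expect_error(parse_velvet_id("NODE_1_len_10_cov_1"), "malformed")
})

test_that("read depth follows C = Ck * L / (L - k + 1)", {
  # independent arithmetic: 17.079645 * 150 / (150 - 71 + 1)
  expect_equal(read_depth(17.079645, 150, 71), 17.079645 * 150 / 80)
  expect_equal(round(read_depth(17.079645, 150, 71), 2), 32.02)
  expect_identical(read_depth(10, 100, 51), 20)
  # k = 1 identity limit and linearity in Ck
  expect_identical(read_depth(7.5, 100, 1), 7.5)
  expect_equal(read_depth(2 * 3.3, 150, 71), 2 * read_depth(3.3, 150, 71))
  expect_error(read_depth(1, 50, 71), "at least k")
})

test_that("classify_novel applies the strict more-than-half rule", {
  set.seed(31)
  ref <- rand_dna(600)
  # verbatim substring -> known
  expect_identical(classify_novel(substr(ref, 100, 299), ref), "known")
  # 200-base contig, longest perfect match 80 -> novel
  c80 <- paste0(substr(ref, 1, 80), rand_dna(120))
  # 200-base contig, 101-base perfect match -> known (strict boundary)
  c101 <- paste0(substr(ref, 1, 101), rand_dna(99))
  c100 <- paste0(substr(ref, 1, 100), rand_dna(100))
  expect_identical(classify_novel(c(c80, c101, c100), ref),
                   c("novel", "known", "novel"))
  # reverse-complement matches count
  expect_identical(classify_novel(revcomp(substr(ref, 100, 299)), ref),
                   "known")
  # monotone: adding references never flips known -> novel
  expect_identical(classify_novel(c80, c(ref, c80)), "known")
  expect_warning(out <- classify_novel("ACGT", character(0)), "novel")
  expect_identical(out, "novel")
})

test_that("add_flanks clamps at contig edges and records truncation", {
  ctg <- rand_dna(300)
  f <- add_flanks(ctg, 50, 70)
  expect_identical(nchar(f), 80L)
  expect_identical(attr(f, "start"), 20L)
  expect_identical(attr(f, "end"), 100L)
  f2 <- add_flanks(ctg, 5, 25)
  expect_identical(nchar(f2), 55L)
  expect_identical(attr(f2, "start"), 0L)
  expect_true(attr(f2, "truncated")[["left"]])
  f3 <- add_flanks(ctg, 50, 70, flank = 0)
  expect_identical(unclass(f3)[1], substr(ctg, 51, 70))
})

test_that("concordant groups require >= 2 samples and obey the mismatch mode", {
  set.seed(17)
  base <- rand_dna(300)
  onemm <- base
  substr(onemm, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                     substr(base, 150, 150))[1]
  contigs <- data.frame(
    sample_id = c("S1", "S2", "S1", "S1", "S3"),
    contig_id = paste0("c", 1:5),
    sequence = c(base, onemm, rand_dna(300), rand_dna(300), rand_dna(300)),
    stringsAsFactors = FALSE
  )
  g1 <- concordant_groups(contigs, max_mismatches = 1)
  expect_length(g1, 1L)
  expect_identical(sort(g1[[1]]$members$contig_id), c("c1", "c2"))
  expect_identical(g1[[1]]$n_samples, 2L)
  g0 <- concordant_groups(contigs, max_mismatches = 0)
  expect_length(g0, 0L)

  # identical contigs but single sample: no group
  solo <- data.frame(sample_id = "S1", contig_id = c("a", "b"),
                     sequence = c(base, base), stringsAsFactors = FALSE)
  expect_length(concordant_groups(solo, 1), 0L)

  # reverse-complement members still group
  rcpair <- data.frame(sample_id = c("S1", "S2"), contig_id = c("a", "b"),
                       sequence = c(base, revcomp(base)),
                       stringsAsFactors = FALSE)
  expect_length(concordant_groups(rcpair, 0), 1L)
})

test_that("0-mismatch groups refine <= 1-mismatch groups; order-invariant", {
  set.seed(53)
  seqs <- character(0)
  samp <- character(0)
  for (locus in 1:3) {
    base <- rand_dna(250)
    for (s in 1:3) {
      v <- base
      if (s == 3) substr(v, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(base, 100, 100))[1]
      seqs <- c(seqs, v)
      samp <- c(samp, paste0("S", s))
    }
  }
  contigs <- data.frame(sample_id = samp,
                        contig_id = paste0("c", seq_along(seqs)),
                        sequence = seqs, stringsAsFactors = FALSE)
  g1 <- concordant_groups(contigs, 1)
  g0 <- concordant_groups(contigs, 0)
  expect_length(g1, 3L)
  expect_true(all(lengths(lapply(g1, function(g) g$members$contig_id)) == 3L))
  # refinement: every 0-mm group is a subset of some 1-mm group
  for (g in g0) {
    inside <- vapply(g1, function(h) {
      all(g$members$contig_id %in% h$members$contig_id)
    }, logical(1))
    expect_identical(sum(inside), 1L)
  }
  # shuffling input order leaves the grouping unchanged
  perm <- sample(nrow(contigs))
  g1p <- concordant_groups(contigs[perm, ], 1)
  ids <- function(gs) sort(vapply(gs, function(g) {
    paste(sort(g$members$contig_id), collapse = ",")
  }, character(1)))
  expect_identical(ids(g1p), ids(g1))
})

test_that("consensus takes majority per column with anchor tie-break", {
  set.seed(61)
  base <- rand_dna(200)
  mut <- base
  substr(mut, 77, 77) <- setdiff(c("A", "C", "G", "T"), substr(base, 77, 77))[1]
  # identical members: consensus is that sequence
  expect_identical(consensus_sequence(c(base, base)), base)
  # 2 vs 1 vote at the mutated column
  expect_identical(consensus_sequence(c(base, base, mut)), base)
  # 1 vs 1: anchor (lexicographically smallest of equal-length) wins
  anchor <- sort(c(base, mut))[1]
  expect_identical(consensus_sequence(c(base, mut)), anchor)
  # overhanging member extends the consensus beyond the anchor
  longer <- paste0(base, rand_dna(20))
  expect_identical(consensus_sequence(c(base, longer)), longer)
})

test_that("cDNA extraction needs >= 2 in-range, non-overlapping exons", {
  ctg <- rand_dna(100)
  exons <- data.frame(start = c(0, 60), end = c(30, 90))
  cdna <- extract_cdna(ctg, exons)
  expect_identical(cdna, paste0(substr(ctg, 1, 30), substr(ctg, 61, 90)))
  expect_error(extract_cdna(ctg, data.frame(start = 0, end = 30)),
               "more than one exon")
  expect_error(extract_cdna(ctg, data.frame(start = c(0, 20), end = c(30, 50))),
               "overlap")
  expect_error(extract_cdna(ctg, data.frame(start = c(0, 60), end = c(30, 120))),
               "range")
  # exons tiling the whole contig give the contig back
  expect_identical(extract_cdna(ctg, data.frame(start = c(0, 50),
                                                end = c(50, 100))), ctg)
})

test_that("match_reads counts perfect matches covering >70% of the shorter", {
  set.seed(71)
  contig <- rand_dna(300)
  other_than <- function(pos) {
    setdiff(c("A", "C", "G", "T"), substr(contig, pos, pos))[1]
  }
  r_exact <- substr(contig, 50, 124)            # 75-base verbatim read
  # 50-base block, then a guaranteed mismatch so the block cannot extend
  r_half <- paste0(substr(contig, 50, 99), other_than(100), rand_dna(24))
  r_rc <- revcomp(substr(contig, 100, 174))
  counts <- match_reads(c(q = contig),
                        list(set1 = c(r_exact, r_half),
                             set2 = c(r_exact, r_rc)))
  expect_identical(counts["q", "set1"], 1L)   # 50 <= 0.7 * 75 -> not counted
  expect_identical(counts["q", "set2"], 2L)
  expect_identical(counts["q", "total"], 3L)
  # same read in 3 sets: total 3, breakdown 1,1,1
  counts3 <- match_reads(c(q = contig),
                         list(a = r_exact, b = r_exact, c = r_exact))
  expect_identical(unname(counts3["q", ]), c(1L, 1L, 1L, 3L))
  # boundary: 53 matching bases of a 75-base read (> 52.5) counts
  r53 <- paste0(substr(contig, 10, 62), other_than(63), rand_dna(21))
  r52 <- paste0(substr(contig, 10, 61), other_than(62), rand_dna(22))
  cb <- match_reads(c(q = contig), list(s = c(r53, r52)))
  expect_identical(cb["q", "s"], 1L)
})
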