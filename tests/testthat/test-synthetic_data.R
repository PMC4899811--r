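test_that("simulation is reproducible bit-exactly under a fixed seed", {
  cfg <- sim_config(seed = 5L, reference_length = 2000L,
                    n_reference_mst_loci = 2L, n_extra_referential_loci = 2L,
                    n_samples = 2L, depth = 10)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_reads(t1, 1), simulate_reads(t2, 1))
  # different samples draw different reads
  expect_false(identical(simulate_reads(t1, 1), simulate_reads(t1, 2)))
  expect_error(sim_config(), "seed")
})

test_that("ground truth lists the configured loci with provable uniqueness", {
  truth <- small_truth()
  cfg <- truth$config
  extra <- truth$loci[!truth$loci$in_reference, ]
  expect_identical(nrow(extra), cfg$n_extra_referential_loci)
  expect_identical(sum(truth$loci$in_reference), cfg$n_reference_mst_loci)
  # every planted locus retrievable by coordinates
  for (i in seq_len(nrow(truth$loci))) {
    l <- truth$loci[i, ]
    src <- if (l$in_reference) truth$reference else truth$extra[[l$segment]]
    expect_identical(substr(src, l$start + 1, l$end),
                     strrep(l$motif, l$copies), info = l$locus_id)
  }
  # extra segments share no 50-mer with the reference (either strand)
  refcat <- paste(c(truth$reference, revcomp(truth$reference)), collapse = "|")
  for (seg in truth$extra) {
    wins <- substring(seg, seq(1, nchar(seg) - 49, by = 17),
                      seq(50, nchar(seg), by = 17))
    expect_false(any(vapply(wins, grepl, logical(1), x = refcat,
                            fixed = TRUE)))
  }
})

test_that("detected repeats in the reference are exactly the planted loci", {
  truth <- small_truth()
  hits <- find_tandem_repeats(truth$reference)
  planted <- truth$loci[truth$loci$in_reference, ]
  # every planted locus is found with the right family...
  for (i in seq_len(nrow(planted))) {
    ov <- hits$start < planted$end[i] & hits$end > planted$start[i]
    expect_true(any(ov & hits$family == planted$family[i]),
                info = planted$locus_id[i])
  }
  # ...and nothing is found outside planted loci (aperiodic background)
  for (j in seq_len(nrow(hits))) {
    ov <- planted$start < hits$end[j] & planted$end > hits$start[j]
    expect_true(any(ov), info = paste("hit", j))
  }
})

test_that("error-free reads are verbatim substrings at the stated coverage", {
  cfg <- sim_config(seed = 9L, reference_length = 3000L,
                    n_reference_mst_loci = 2L, n_extra_referential_loci = 2L,
                    n_samples = 1L, depth = 30,
                    substitution_error_rate = 0, n_rate = 0)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 1)
  expect_true(all(nchar(reads$sequence) == 150L))
  expect_true(all(reads$qualities == strrep(intToUtf8(40L + 33L), 150L)))
  world <- paste(c(truth$reference, truth$extra,
                   revcomp(c(truth$reference, truth$extra))), collapse = "|")
  idx <- sample(nrow(reads), 40)
  expect_true(all(vapply(reads$sequence[idx], grepl, logical(1), x = world,
                         fixed = TRUE)))
  # read-count identity: depth * total_length / read_length within 5%
  total_len <- nchar(truth$reference) + sum(nchar(truth$extra))
  expected_reads <- 30 * total_len / 150
  expect_lt(abs(nrow(reads) - expected_reads) / expected_reads, 0.05)
})

test_that("N masking hits the configured rate", {
  cfg <- sim_config(seed = 13L, reference_length = 3000L,
                    n_reference_mst_loci = 0L, n_extra_referential_loci = 2L,
                    n_samples = 1L, depth = 30,
                    substitution_error_rate = 0, n_rate = 0.01)
  reads <- simulate_reads(simulate_genome(cfg), 1)
  nn <- sum(vapply(gregexpr("N", reads$sequence, fixed = TRUE),
                   function(g) sum(g > 0), numeric(1)))
  total <- sum(nchar(reads$sequence))
  # binomial tolerance: 4 sigma around 1%
  expect_lt(abs(nn / total - 0.01), 4 * sqrt(0.01 * 0.99 / total))
})

test_that("naive_map verdicts follow the substitution budget", {
  truth <- small_truth()
  ref <- truth$reference
  clean <- substr(ref, 501, 650)
  two_sub <- clean
  substr(two_sub, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clean, 10, 10))[1]
  substr(two_sub, 80, 80) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clean, 80, 80))[1]
  three_sub <- two_sub
  substr(three_sub, 140, 140) <- setdiff(c("A", "C", "G", "T"),
                                         substr(two_sub, 140, 140))[1]
  extra_read <- substr(truth$extra[[1]], 101, 250)
  res <- naive_map(c(clean, revcomp(clean), two_sub, three_sub, extra_read),
                   ref, max_mismatches = 2)
  expect_identical(nrow(res$mapped), 3L)
  expect_identical(nrow(res$unmapped), 2L)
  expect_true(three_sub %in% res$unmapped$sequence)
  expect_true(extra_read %in% res$unmapped$sequence)
})

test_that("greedy assembly reconstructs a tiled segment and converts coverage", {
  set.seed(41)
  segment <- rand_dna(1000)
  starts <- seq(1, nchar(segment) - 149, by = 5)  # 30x interior coverage
  reads <- substring(segment, starts, starts + 149)
  ctg <- greedy_assemble(reads, k = 71)
  expect_identical(nrow(ctg), 1L)
  expect_true(ctg$sequence %in% c(segment, revcomp(segment)))
  v <- parse_velvet_id(ctg$contig_id)
  expect_identical(v$length, nchar(segment))
  expect_equal(v$coverage, ctg$coverage, tolerance = 1e-6)
  # coverage identity through the printed formula: uniform 30x error-free
  # tiling should convert back to ~30 (edge losses shrink with length)
  depth <- read_depth(ctg$coverage, 150, 71)
  expect_lt(abs(depth - 30) / 30, 0.15)

  # a repeat-bearing extra segment also assembles to one contig
  segment2 <- small_truth()$extra[[2]]
  st2 <- seq(1, nchar(segment2) - 149, by = 10)
  ctg2 <- greedy_assemble(substring(segment2, st2, st2 + 149))
  expect_identical(nrow(ctg2), 1L)
  expect_true(ctg2$sequence %in% c(segment2, revcomp(segment2)))

  # non-overlapping reads stay separate
  two <- greedy_assemble(c(substr(segment, 1, 100),
                           substr(segment, 201, 300)))
  expect_identical(nrow(two), 2L)
})

test_that("FASTQ written by the simulator round-trips through read_fastq", {
  truth <- small_truth()
  reads <- simulate_reads(truth, 1)
  r1 <- reads[reads$mate == 1L, c("id", "sequence", "qualities")]
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(r1, path)
  back <- read_fastq(path)
  rownames(r1) <- NULL
  expect_identical(back, r1)
})
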