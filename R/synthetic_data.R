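#' Simulation configuration
#'
#' Describes the synthetic world the end-to-end tests run in: a small
#' reference genome with planted microsatellite loci, plus extra-referential
#' segments (absent from the reference, as centromeric repeat arrays are
#' absent from a genome assembly) dominated by the pentameric motifs AATGG
#' and GTGGA; 150-base paired-end DNA reads and 75-base RNA-like reads.
#'
#' Defaults mirror the study design at desk scale: 6 samples, 20 shared
#' extra-referential pentamer loci, 30x depth, 150-base paired reads,
#' substitution error rate 1e-3 (a Q30 instrument), N-masking rate 5e-4.
#' The reference motif pool deliberately excludes AATGG/GTGGA: their absence
#' from the reference is exactly what makes the extra-referential reads
#' unmapped.
#'
#' @param seed Mandatory integer seed; all generators are bit-reproducible
#'   given the seed.
#' @param reference_length Reference genome length in bases.
#' @param n_reference_mst_loci Microsatellite loci planted in the reference.
#' @param n_extra_referential_loci Extra-referential repeat segments.
#' @param motif_pool Named numeric vector of motif weights for
#'   extra-referential loci (pentamer-dominated by default).
#' @param reference_motif_pool Motif weights for reference loci.
#' @param n_samples Number of DNA samples.
#' @param read_length DNA read length (paired-end).
#' @param rna_read_length RNA-like read length.
#' @param depth Fold coverage per sample.
#' @param substitution_error_rate Per-base substitution probability.
#' @param n_rate Per-base probability of masking to N.
#' @param extra_segment_length Length of each extra-referential segment.
#' @param fragment_length Sequenced fragment length (R1 + R2, no gap).
#' @param repeat_copies Integer range (length-2) of tandem copies planted at
#'   extra-referential loci; kept short enough that every read spans unique
#'   flank, so assembly is unambiguous.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       reference_length = 10000L,
                       n_reference_mst_loci = 12L,
                       n_extra_referential_loci = 20L,
                       motif_pool = c(AATGG = 5, GTGGA = 3, AATGC = 1,
                                      AACCT = 1),
                       reference_motif_pool = c(A = 1, AC = 2, AAG = 1,
                                                AAT = 2, AGAT = 2, AAAT = 1,
                                                AATG = 1),
                       n_samples = 6L,
                       read_length = 150L,
                       rna_read_length = 75L,
                       depth = 30,
                       substitution_error_rate = 0.001,
                       n_rate = 5e-4,
                       extra_segment_length = 400L,
                       fragment_length = 300L,
                       repeat_copies = c(16L, 22L)) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(substitution_error_rate, n_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  stopifnot(fragment_length >= 2L * read_length - read_length %/% 2L,
            extra_segment_length >= fragment_length)
  structure(list(
    seed = as.integer(seed),
    reference_length = as.integer(reference_length),
    n_reference_mst_loci = as.integer(n_reference_mst_loci),
    n_extra_referential_loci = as.integer(n_extra_referential_loci),
    motif_pool = motif_pool,
    reference_motif_pool = reference_motif_pool,
    n_samples = as.integer(n_samples),
    read_length = as.integer(read_length),
    rna_read_length = as.integer(rna_read_length),
    depth = depth,
    substitution_error_rate = substitution_error_rate,
    n_rate = n_rate,
    extra_segment_length = as.integer(extra_segment_length),
    fragment_length = as.integer(fragment_length),
    repeat_copies = as.integer(repeat_copies)
  ), class = "sim_config")
}

# aperiodic random DNA: rejection-sample until no interval reaches the
# repeat-reporting threshold
.aperiodic_dna <- function(n, params = repeat_params(), max_iter = 50L) {
  s <- random_dna(n)
  for (iter in seq_len(max_iter)) {
    hits <- find_tandem_repeats(s, params)
    if (nrow(hits) == 0L) return(s)
    chars <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(hits))) {
      a <- max(1L, hits$start[i] - 3L)
      b <- min(n, hits$end[i] + 3L)
      chars[a:b] <- sample(c("A", "C", "G", "T"), b - a + 1L, replace = TRUE)
    }
    s <- paste(chars, collapse = "")
  }
  stop("could not generate aperiodic background")
}

.weighted_motif <- function(pool) {
  sample(names(pool), 1L, prob = pool)
}

#' Simulate a reference genome and extra-referential segments
#'
#' The reference is aperiodic background (rejection-sampled so it contains no
#' interval reaching the repeat-reporting threshold) with
#' `n_reference_mst_loci` planted microsatellites.  Each extra-referential
#' segment carries one pentamer-pool locus with at least 30 unique flanking
#' bases on each side, and is checked to share no 50-base substring with the
#' reference (either strand), so a mapper verdict of "unmapped" is provable
#' ground truth rather than a heuristic.
#'
#' @param config A [sim_config()].
#' @return List of class `gme_truth` with elements `reference` (string),
#'   `extra` (named character vector of segments), `loci` (data frame:
#'   `locus_id`, `segment`, `start`, `end`, `motif`, `family`, `copies`,
#'   `in_reference`), `presence` (samples x extra-loci logical matrix) and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  params <- repeat_params()

  n_ref_loci <- config$n_reference_mst_loci
  ref_len <- config$reference_length
  spacing_needed <- n_ref_loci * 220L
  if (spacing_needed > ref_len) stop("too many reference loci for the length")

  reference <- .aperiodic_dna(ref_len, params)
  loci <- list()
  if (n_ref_loci > 0L) {
    # evenly spaced slots with jitter keep loci (and their flanks) disjoint
    slot <- ref_len %/% n_ref_loci
    for (i in seq_len(n_ref_loci)) {
      motif <- .weighted_motif(config$reference_motif_pool)
      p <- nchar(motif)
      copies <- max(p + 8L, sample(24:60, 1L)) %/% p + 1L
      run <- strrep(motif, copies)
      run_len <- nchar(run)
      pos <- (i - 1L) * slot + sample(40:(slot - run_len - 40L), 1L)
      substr(reference, pos + 1L, pos + run_len) <- run
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("ref_locus_%02d", i), segment = "reference",
        start = pos, end = pos + run_len, motif = motif,
        family = canonical_name(motif), copies = copies,
        in_reference = TRUE, stringsAsFactors = FALSE)
    }
  }

  refcat <- paste(c(reference, revcomp(reference)), collapse = "|")
  extra <- character(config$n_extra_referential_loci)
  names(extra) <- sprintf("extra_%02d", seq_along(extra))
  for (i in seq_len(config$n_extra_referential_loci)) {
    repeat {
      motif <- .weighted_motif(config$motif_pool)
      p <- nchar(motif)
      copies <- sample(config$repeat_copies[1L]:config$repeat_copies[2L], 1L)
      run <- strrep(motif, copies)
      run_len <- nchar(run)
      rest <- config$extra_segment_length - run_len
      left_len <- rest %/% 2L
      seg <- paste0(.aperiodic_dna(left_len, params), run,
                    .aperiodic_dna(rest - left_len, params))
      # provably extra-referential: no 50-mer shared with the reference
      wins <- substring(seg, 1:(nchar(seg) - 49L), 50:nchar(seg))
      shared <- any(vapply(wins, function(w) grepl(w, refcat, fixed = TRUE),
                           logical(1)))
      if (!shared) {
        extra[i] <- seg
        loci[[length(loci) + 1L]] <- data.frame(
          locus_id = sprintf("extra_locus_%02d", i),
          segment = names(extra)[i], start = left_len,
          end = left_len + run_len, motif = motif,
          family = canonical_name(motif), copies = copies,
          in_reference = FALSE, stringsAsFactors = FALSE)
        break
      }
    }
  }

  presence <- matrix(TRUE, nrow = config$n_samples,
                     ncol = config$n_extra_referential_loci,
                     dimnames = list(sprintf("S%d", seq_len(config$n_samples)),
                                     names(extra)))
  structure(list(reference = reference, extra = extra,
                 loci = do.call(rbind, loci), presence = presence,
                 config = config),
            class = "gme_truth")
}

.phred_char <- function(q) intToUtf8(q + 33L)

# apply substitution errors and N masking; returns list(seq, qual)
.corrupt <- function(seqs, err, n_rate, base_q) {
  out_seq <- character(length(seqs))
  out_qual <- character(length(seqs))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    L <- length(ch)
    q <- rep.int(base_q, L)
    if (err > 0) {
      sub <- which(stats::runif(L) < err)
      for (j in sub) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    }
    if (n_rate > 0) {
      nn <- which(stats::runif(L) < n_rate)
      ch[nn] <- "N"
      q[nn] <- 2L
    }
    out_seq[i] <- paste(ch, collapse = "")
    out_qual[i] <- .phred_char(q)
  }
  list(seq = out_seq, qual = out_qual)
}

#' Simulate paired-end DNA reads for one sample
#'
#' Fragments of `fragment_length` bases are drawn uniformly from the
#' reference and from every extra-referential segment present in the sample;
#' read 1 is the fragment prefix, read 2 the reverse complement of the
#' fragment suffix.  Substitution errors and N masking are applied at the
#' configured rates; base qualities encode the error model (Phred of the
#' per-base error probability, N bases at Q2).
#'
#' @param truth A `gme_truth` from [simulate_genome()].
#' @param sample_index Integer sample number (1..`n_samples`); seeds a
#'   sample-specific RNG stream derived from the master seed.
#' @return Data frame with columns `id`, `sequence`, `qualities`, `mate`,
#'   `pair_id`.
#' @export
simulate_reads <- function(truth, sample_index) {
  stopifnot(inherits(truth, "gme_truth"))
  cfg <- truth$config
  set.seed((cfg$seed + 7919L * as.integer(sample_index)) %% .Machine$integer.max)
  sources <- c(reference = truth$reference,
               truth$extra[truth$presence[sample_index, ]])
  frag <- cfg$fragment_length
  rl <- cfg$read_length
  ids <- seqs1 <- seqs2 <- character(0)
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    L <- nchar(src)
    n_frag <- max(1L, round(L * cfg$depth / frag))
    starts <- sample.int(L - frag + 1L, n_frag, replace = TRUE)
    f <- substring(src, starts, starts + frag - 1L)
    seqs1 <- c(seqs1, substr(f, 1L, rl))
    seqs2 <- c(seqs2, revcomp(substring(f, frag - rl + 1L, frag)))
    ids <- c(ids, sprintf("S%d_%s_frag%05d", sample_index, names(sources)[si],
                          seq_along(starts)))
  }
  base_q <- if (cfg$substitution_error_rate > 0) {
    as.integer(round(-10 * log10(cfg$substitution_error_rate)))
  } else 40L
  r1 <- .corrupt(seqs1, cfg$substitution_error_rate, cfg$n_rate, base_q)
  r2 <- .corrupt(seqs2, cfg$substitution_error_rate, cfg$n_rate, base_q)
  data.frame(
    id = c(paste0(ids, "/1"), paste0(ids, "/2")),
    sequence = c(r1$seq, r2$seq),
    qualities = c(r1$qual, r2$qual),
    mate = rep(c(1L, 2L), each = length(ids)),
    pair_id = c(ids, ids),
    stringsAsFactors = FALSE
  )
}

#' Simulate RNA-like reads from selected extra-referential segments
#'
#' Short (75-base by default) single-end reads drawn uniformly from a subset
#' of extra-referential segments, used to exercise [match_reads()] with
#' known expected counts.
#'
#' @param truth A `gme_truth`.
#' @param segments Names of extra segments to express (default: first 5).
#' @param depth Fold coverage (default 20).
#' @param set_id Label for the read set (also seeds its RNG stream).
#' @return Data frame with `id`, `sequence`, `qualities`.
#' @export
simulate_rna_reads <- function(truth, segments = NULL, depth = 20,
                               set_id = 1L) {
  cfg <- truth$config
  if (is.null(segments)) {
    segments <- names(truth$extra)[seq_len(min(5L, length(truth$extra)))]
  }
  set.seed((cfg$seed + 104729L * as.integer(set_id)) %% .Machine$integer.max)
  rl <- cfg$rna_read_length
  ids <- seqs <- character(0)
  for (sg in segments) {
    src <- truth$extra[[sg]]
    n_reads <- max(1L, round(nchar(src) * depth / rl))
    starts <- sample.int(nchar(src) - rl + 1L, n_reads, replace = TRUE)
    seqs <- c(seqs, substring(src, starts, starts + rl - 1L))
    ids <- c(ids, sprintf("rna%d_%s_%04d", set_id, sg, seq_len(n_reads)))
  }
  out <- .corrupt(seqs, cfg$substitution_error_rate, 0, 30L)
  data.frame(id = ids, sequence = out$seq, qualities = out$qual,
             stringsAsFactors = FALSE)
}

#' Partition reads into mapped and unmapped against a reference
#'
#' A read is mapped when it (or its reverse complement) occurs in the
#' reference with at most `max_mismatches` substitutions (N counts as a
#' mismatch).  Candidate placements come from exact seed k-mers: a read with
#' at most `max_mismatches` bad positions must contain an error-free seed
#' among `max_mismatches + 1` disjoint probes, so the verdict is exact for
#' reads of at least `(max_mismatches + 1) * k` bases.
#'
#' @param reads Data frame with a `sequence` column, or character vector.
#' @param reference Reference sequence (single string or named vector; the
#'   first element is used... all elements are concatenated for seeding).
#' @param max_mismatches Substitution budget (default 2).
#' @return `list(mapped=, unmapped=)`, each the corresponding subset of
#'   `reads`.
#' @export
naive_map <- function(reads, reference, max_mismatches = 2L) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("r", seq_along(reads)), sequence = reads,
                        stringsAsFactors = FALSE)
  }
  refs <- unlist(reference, use.names = FALSE)
  seqs <- reads$sequence
  if (nrow(reads) == 0L) return(list(mapped = reads, unmapped = reads))
  min_len <- min(nchar(seqs))
  k <- max(12L, min(31L, min_len %/% (max_mismatches + 1L)))

  # seed index over both strands of every reference sequence
  index <- new.env(parent = emptyenv(), size = 4L * sum(nchar(refs)))
  strands <- list()
  sid <- 0L
  for (rseq in refs) for (strand_seq in c(rseq, revcomp(rseq))) {
    sid <- sid + 1L
    strands[[sid]] <- utf8ToInt(strand_seq)
    n <- nchar(strand_seq)
    if (n < k) next
    kms <- substring(strand_seq, 1:(n - k + 1L), k:n)
    for (pos in seq_along(kms)) {
      key <- kms[pos]
      index[[key]] <- c(index[[key]], sid, pos)
    }
  }

  mapped <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- seqs[i]
    L <- nchar(r)
    if (L < k) next
    xr <- utf8ToInt(r)
    n_probe <- max_mismatches + 1L
    probes <- unique(pmin(1L + floor((seq_len(n_probe) - 1L) * L / n_probe),
                          L - k + 1L))
    ok <- FALSE
    for (p in probes) {
      hit <- index[[substr(r, p, p + k - 1L)]]
      if (is.null(hit)) next
      for (h in seq(1L, length(hit), by = 2L)) {
        sidx <- hit[h]; pos <- hit[h + 1L]
        astart <- pos - (p - 1L)
        x <- strands[[sidx]]
        if (astart < 1L || astart + L - 1L > length(x)) next
        if (sum(x[astart:(astart + L - 1L)] != xr) <= max_mismatches) {
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    mapped[i] <- ok
  }
  list(mapped = reads[mapped, , drop = FALSE],
       unmapped = reads[!mapped, , drop = FALSE])
}

#' Greedy exact-overlap assembly with Velvet-style contig IDs
#'
#' Merges reads (considered on both strands) by maximal exact suffix-prefix
#' overlaps of at least `min_overlap` bases, largest overlap first, each read
#' extended at most once on each side; reverse-complement duplicate contigs
#' and contained contigs are removed.  Per-contig k-mer coverage `Ck` is the
#' total number of read k-mers assigned to the contig divided by
#' `length - k + 1`, and the ID is formatted `NODE_<n>_length_<L>_cov_<Ck>`
#' so that [parse_velvet_id()] and [read_depth()] run end to end.
#'
#' @param reads Character vector of read sequences (or data frame with a
#'   `sequence` column).
#' @param min_overlap Minimum exact overlap (default 31).
#' @param k K-mer (hash) length for the coverage bookkeeping (default 71, an
#'   odd value so a k-mer can never be its own reverse complement).
#' @return Data frame with columns `contig_id`, `node_id`, `length`,
#'   `coverage`, `sequence`, sorted by decreasing length.
#' @export
greedy_assemble <- function(reads, min_overlap = 31L, k = 71L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- reads[nchar(reads) >= min_overlap]
  empty <- data.frame(contig_id = character(0), node_id = integer(0),
                      length = integer(0), coverage = numeric(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)

  seqs <- sort(unique(c(reads, revcomp(reads))))
  n <- length(seqs)
  lens <- nchar(seqs)

  # overlap edges via an index of read prefixes of length min_overlap
  pref_index <- new.env(parent = emptyenv(), size = 2L * n)
  for (i in seq_len(n)) {
    key <- substr(seqs[i], 1L, min_overlap)
    pref_index[[key]] <- c(pref_index[[key]], i)
  }
  edges <- list()
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- lens[i]
    for (t in 2L:(L - min_overlap + 1L)) {
      cand <- pref_index[[substr(s, t, t + min_overlap - 1L)]]
      if (is.null(cand)) next
      olen <- L - t + 1L
      suf <- substr(s, t, L)
      for (j in cand) {
        if (j == i) next
        if (lens[j] > olen && substr(seqs[j], 1L, olen) == suf) {
          edges[[length(edges) + 1L]] <- c(i, j, olen)
          break  # longest overlap for this (i, .) found at smallest t
        }
      }
      if (length(edges) > 0L &&
          edges[[length(edges)]][1L] == i &&
          edges[[length(edges)]][3L] == olen) break
    }
  }

  succ <- rep(NA_integer_, n)
  pred <- rep(NA_integer_, n)
  olap <- rep(0L, n)
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    em <- em[order(-em[, 3L], em[, 1L], em[, 2L]), , drop = FALSE]
    parent <- .uf_new(n)
    for (r in seq_len(nrow(em))) {
      i <- em[r, 1L]; j <- em[r, 2L]
      if (!is.na(succ[i]) || !is.na(pred[j])) next
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri == rj) next  # would close a cycle
      succ[i] <- j; pred[j] <- i; olap[i] <- em[r, 3L]
      parent[ri] <- rj
    }
  }

  starts <- which(is.na(pred))
  contigs <- character(0)
  for (s0 in starts) {
    ctg <- seqs[s0]
    i <- s0
    while (!is.na(succ[i])) {
      j <- succ[i]
      ctg <- paste0(ctg, substr(seqs[j], olap[i] + 1L, lens[j]))
      i <- j
    }
    contigs <- c(contigs, ctg)
  }
  # strand dedup: keep the lexicographically smaller of contig / revcomp
  contigs <- unique(pmin(contigs, revcomp(contigs)))
  # containment dedup
  ord <- order(-nchar(contigs))
  contigs <- contigs[ord]
  keep <- rep(TRUE, length(contigs))
  for (i in seq_along(contigs)) {
    if (!keep[i]) next
    for (j in seq_along(contigs)) {
      if (i == j || !keep[j] || nchar(contigs[j]) > nchar(contigs[i])) next
      if (nchar(contigs[j]) < nchar(contigs[i]) &&
          (grepl(contigs[j], contigs[i], fixed = TRUE) ||
           grepl(revcomp(contigs[j]), contigs[i], fixed = TRUE))) {
        keep[j] <- FALSE
      }
    }
  }
  contigs <- contigs[keep]

  # assign each input read to the first contig containing it (either strand)
  kmer_total <- numeric(length(contigs))
  ctg_cat <- contigs
  for (r in reads) {
    hit <- 0L
    for (ci in seq_along(ctg_cat)) {
      if (grepl(r, ctg_cat[ci], fixed = TRUE) ||
          grepl(revcomp(r), ctg_cat[ci], fixed = TRUE)) {
        hit <- ci
        break
      }
    }
    if (hit > 0L && nchar(r) >= k) {
      kmer_total[hit] <- kmer_total[hit] + (nchar(r) - k + 1L)
    }
  }
  lens_c <- nchar(contigs)
  cov <- ifelse(lens_c >= k, kmer_total / (lens_c - k + 1L), 0)
  out <- data.frame(node_id = seq_along(contigs), length = lens_c,
                    coverage = cov, sequence = contigs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  out$node_id <- seq_len(nrow(out))
  out$contig_id <- sprintf("NODE_%d_length_%d_cov_%.6f", out$node_id,
                           out$length, out$coverage)
  rownames(out) <- NULL
  out[c("contig_id", "node_id", "length", "coverage", "sequence")]
}
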