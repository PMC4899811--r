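#' Parse a Velvet-style contig identifier
#'
#' IDs look like `NODE_35_length_226_cov_17.079645`.
#'
#' @param id_string A single contig ID.
#' @return `list(node_id=, length=, coverage=)`.
#' @export
parse_velvet_id <- function(id_string) {
  .stopifnot_scalar_string(id_string, "id_string")
  parts <- strsplit(id_string, "_", fixed = TRUE)[[1]]
  if (length(parts) != 6L || parts[1] != "NODE" || parts[3] != "length" ||
      parts[5] != "cov") {
    stop("malformed Velvet ID '", id_string,
         "': expected NODE_<int>_length_<int>_cov_<real>")
  }
  node <- suppressWarnings(as.integer(parts[2]))
  if (is.na(node)) stop("malformed Velvet ID: node field '", parts[2],
                        "' is not an integer")
  len <- suppressWarnings(as.integer(parts[4]))
  if (is.na(len)) stop("malformed Velvet ID: length field '", parts[4],
                       "' is not an integer")
  cov <- suppressWarnings(as.numeric(parts[6]))
  if (is.na(cov)) stop("malformed Velvet ID: cov field '", parts[6],
                       "' is not a number")
  list(node_id = node, length = len, coverage = cov)
}

#' Convert Velvet k-mer coverage to read depth
#'
#' `C = Ck * L / (L - k + 1)` where `Ck` is the contig k-mer coverage, `L`
#' the average read length and `k` the assembly k-mer (hash) length.
#'
#' @param Ck Contig k-mer coverage (non-negative real, vectorised).
#' @param L Average read length.
#' @param k Assembly k-mer length, `1 <= k <= L`.
#' @return Read depth `C`.
#' @export
#' @examples
#' read_depth(17.079645, 150, 71)  # 32.02...
read_depth <- function(Ck, L, k) {
  if (k < 1) stop("k must be at least 1")
  if (L < k) stop("average read length L must be at least k")
  Ck * L / (L - k + 1)
}

# longest run with at most max_mm mismatches given mismatch positions
# (mpos, 1-based within an overlap of length len)
.longest_block <- function(mpos, len, max_mm) {
  if (len <= 0L) return(0L)
  if (length(mpos) <= max_mm) return(len)
  b <- c(0L, mpos, len + 1L)
  # window spanning max_mm consecutive mismatches plus flanks
  w <- seq_len(length(b) - max_mm - 1L)
  max(b[w + max_mm + 1L] - b[w] - 1L)
}

# best ungapped block between integer-coded sequences at every offset in
# `offsets` (offset = position of yb[1] within xa, may be <= 0); returns the
# longest block with at most max_mm mismatches
.best_block_at <- function(xa, xb, offsets, max_mm) {
  na <- length(xa); nb <- length(xb)
  best <- 0L
  for (d in unique(offsets)) {
    a1 <- max(1L, d); a2 <- min(na, d + nb - 1L)
    if (a2 - a1 + 1L <= best) next
    ia <- a1:a2
    ib <- ia - d + 1L
    mpos <- which(xa[ia] != xb[ib])
    blk <- .longest_block(mpos, length(ia), max_mm)
    if (blk > best) best <- blk
  }
  best
}

# k-mer start positions shared between two strings -> candidate offsets
.anchor_offsets <- function(a, b, k = 31L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(integer(0))
  ka <- substring(a, 1:(na - k + 1L), k:na)
  kb <- substring(b, 1:(nb - k + 1L), k:nb)
  m <- match(kb, ka)
  hit <- which(!is.na(m))
  if (length(hit) == 0L) return(integer(0))
  unique(m[hit] - hit + 1L)
}

#' Best ungapped alignment block between two sequences
#'
#' Searches both orientations of `b` for the longest contiguous block
#' containing at most `max_mismatches` substitutions.  Long sequence pairs
#' are anchored on shared 31-mers (any qualifying block of 63+ bases with at
#' most one mismatch must contain an exact 31-mer); shorter pairs fall back
#' to an exhaustive offset scan.
#'
#' @param a,b DNA strings.
#' @param max_mismatches Allowed substitutions inside the block (0 or 1 for
#'   concordance calling).
#' @return Integer block length (0 when nothing aligns).
#' @export
best_ungapped_block <- function(a, b, max_mismatches = 1L) {
  xa <- utf8ToInt(a)
  best <- 0L
  exhaustive <- min(nchar(a), nchar(b)) < 89L
  for (bseq in c(b, revcomp(b))) {
    xb <- utf8ToInt(bseq)
    offsets <- if (exhaustive) {
      (2L - length(xb)):length(xa)
    } else {
      .anchor_offsets(a, bseq)
    }
    if (length(offsets) == 0L) next
    blk <- .best_block_at(xa, xb, offsets, max_mismatches)
    if (blk > best) best <- blk
  }
  best
}

#' Classify contigs as known or novel against reference sets
#'
#' A contig is *known* when some reference sequence contains a perfect
#' (100% identity, ungapped) match, on either strand, to a contig substring
#' strictly longer than half the contig length; otherwise it is *novel*.
#' This exact-substring rule is the deterministic equivalent of the
#' BLAST-based "100% identity over more than half the query" criterion.
#'
#' @param contigs Character vector of contig sequences.
#' @param known_sets Character vector (or list of vectors) of reference
#'   sequences; with an empty set every contig is novel, with a warning.
#' @return Character vector `"known"`/`"novel"` parallel to `contigs`.
#' @export
classify_novel <- function(contigs, known_sets) {
  refs <- unlist(known_sets, use.names = FALSE)
  if (length(refs) == 0L) {
    warning("no reference sequences supplied; all contigs reported novel")
    return(rep("novel", length(contigs)))
  }
  refcat <- paste(c(refs, revcomp(refs)), collapse = "|")
  vapply(contigs, function(ctg) {
    L <- nchar(ctg)
    t <- L %/% 2L + 1L  # strictly more than half
    if (t > L) t <- L
    for (s in seq_len(L - t + 1L)) {
      if (grepl(substr(ctg, s, s + t - 1L), refcat, fixed = TRUE)) {
        return("known")
      }
    }
    "novel"
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a repeat locus with flanking bases from its contig
#'
#' @param contig Contig sequence.
#' @param start,end 0-based half-open repeat interval within the contig.
#' @param flank Bases added on each side (default 30); truncated at contig
#'   edges, with truncation recorded in the `truncated` attribute.
#' @return Substring with attributes `start`, `end` (0-based half-open
#'   extracted interval) and `truncated`.
#' @export
add_flanks <- function(contig, start, end, flank = 30L) {
  L <- nchar(contig)
  stopifnot(start >= 0, end <= L, start < end)
  s <- as.integer(max(0, start - flank))
  e <- as.integer(min(L, end + flank))
  out <- substr(contig, s + 1L, e)
  attr(out, "start") <- s
  attr(out, "end") <- e
  attr(out, "truncated") <- c(left = s > start - flank, right = e < end + flank)
  out
}

# minimal union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }

#' Group novel contigs observed in two or more samples
#'
#' Two contigs are linked when an ungapped alignment (either strand) has at
#' most `max_mismatches` substitutions and covers more than 70% of the length
#' of at least one of the two (the shorter one suffices).  Groups are the
#' connected components of this link graph; only components spanning at least
#' two distinct samples are returned.  Run once with `max_mismatches = 0` and
#' once with `1` to obtain the usual pair of concordance lists.
#'
#' @param contigs Data frame with columns `sample_id`, `contig_id`,
#'   `sequence` (novel contigs pooled over samples).
#' @param max_mismatches 0 or 1.
#' @param min_cover Fraction of the shorter contig an alignment must exceed
#'   (default 0.7).
#' @return List of class `concordant_groups`; each element has `group_id`,
#'   `members` (row subset of `contigs`), `n_samples` and `mismatch_mode`.
#' @export
concordant_groups <- function(contigs, max_mismatches = 1L, min_cover = 0.7) {
  stopifnot(all(c("sample_id", "contig_id", "sequence") %in% names(contigs)))
  n <- nrow(contigs)
  if (n == 0L) return(structure(list(), class = "concordant_groups"))
  contigs <- contigs[order(contigs$sample_id, contigs$contig_id), ,
                     drop = FALSE]
  rownames(contigs) <- NULL
  seqs <- contigs$sequence
  lens <- nchar(seqs)

  # candidate pairs: share a 31-mer on either strand, or involve a contig
  # too short for the anchor guarantee (then tested exhaustively)
  k <- 31L
  keys <- lapply(seq_len(n), function(i) {
    s <- seqs[i]
    if (lens[i] < k) return(character(0))
    km <- substring(s, 1:(lens[i] - k + 1L), k:lens[i])
    unique(pmin(km, revcomp(km)))
  })
  bucket <- split(rep(seq_len(n), lengths(keys)), unlist(keys))
  pairs <- unique(do.call(rbind, lapply(bucket, function(ix) {
    ix <- sort(unique(ix))
    if (length(ix) < 2L) return(NULL)
    t(utils::combn(ix, 2L))
  })))
  short <- which(lens < 89L)
  if (length(short) > 0L) {
    extra <- do.call(rbind, lapply(short, function(i) {
      js <- setdiff(seq_len(n), i)
      cbind(pmin(i, js), pmax(i, js))
    }))
    pairs <- unique(rbind(pairs, extra))
  }

  parent <- .uf_new(n)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri == rj) next
      blk <- best_ungapped_block(seqs[i], seqs[j], max_mismatches)
      if (blk > min_cover * min(lens[i], lens[j])) {
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), comp)
  out <- list()
  gid <- 0L
  for (g in groups) {
    samp <- unique(contigs$sample_id[g])
    if (length(g) < 2L || length(samp) < 2L) next
    gid <- gid + 1L
    out[[gid]] <- list(group_id = sprintf("group_%03d", gid),
                       members = contigs[g, , drop = FALSE],
                       n_samples = length(samp),
                       mismatch_mode = as.integer(max_mismatches))
  }
  structure(out, class = "concordant_groups")
}

#' Consensus sequence of a concordant group
#'
#' Star alignment anchored on the longest member (ties broken toward the
#' lexicographically smallest sequence): every other member is placed at its
#' best ungapped offset/orientation against the anchor and a per-column
#' majority vote is taken, ties resolved toward the anchor's base (or the
#' alphabetically smallest base on columns the anchor does not cover).
#' Members whose best placement matches the anchor poorly (under 90% identity
#' over the overlap) are flagged irreconcilable and excluded from the vote;
#' if none align, the anchor itself is returned with attribute
#' `irreconcilable`.
#'
#' @param group One element of [concordant_groups()] output, or a character
#'   vector of member sequences.
#' @return Consensus DNA string (length at least the anchor length).
#' @export
consensus_sequence <- function(group) {
  seqs <- if (is.character(group)) group else group$members$sequence
  stopifnot(length(seqs) >= 1L)
  ord <- order(-nchar(seqs), seqs)
  anchor <- seqs[ord[1L]]
  others <- seqs[ord[-1L]]
  xa <- utf8ToInt(anchor)
  na <- length(xa)
  placements <- list(list(x = xa, offset = 1L))
  irreconcilable <- character(0)
  for (s in others) {
    best <- list(score = -Inf)
    for (bseq in c(s, revcomp(s))) {
      xb <- utf8ToInt(bseq)
      nb <- length(xb)
      offs <- .anchor_offsets(anchor, bseq, k = min(31L, min(na, nb)))
      if (length(offs) == 0L) offs <- (2L - nb):na
      for (d in offs) {
        a1 <- max(1L, d); a2 <- min(na, d + nb - 1L)
        if (a1 > a2) next
        ov <- a2 - a1 + 1L
        matches <- sum(xa[a1:a2] == xb[(a1:a2) - d + 1L])
        if (matches > best$score) best <- list(score = matches, x = xb,
                                               offset = d, overlap = ov)
      }
    }
    if (!is.finite(best$score) || best$score < 0.9 * best$overlap) {
      irreconcilable <- c(irreconcilable, s)
      next
    }
    placements[[length(placements) + 1L]] <- best[c("x", "offset")]
  }
  lo <- min(vapply(placements, `[[`, integer(1), "offset"))
  hi <- max(vapply(placements, function(p) p$offset + length(p$x) - 1L,
                   integer(1)))
  width <- hi - lo + 1L
  counts <- matrix(0L, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)
  for (p in placements) {
    cols <- (p$offset - lo + 1L):(p$offset - lo + length(p$x))
    for (b in seq_along(codes)) {
      sel <- cols[p$x == codes[b]]
      counts[b, sel] <- counts[b, sel] + 1L
    }
  }
  anchor_cols <- (1L - lo + 1L):(na - lo + 1L)
  cons <- character(width)
  for (j in seq_len(width)) {
    cnt <- counts[, j]
    winners <- names(cnt)[cnt == max(cnt)]
    if (length(winners) > 1L && j %in% anchor_cols) {
      ab <- substr(anchor, j - (1L - lo), j - (1L - lo))
      if (ab %in% winners) winners <- ab
    }
    cons[j] <- winners[1L]
  }
  out <- paste(cons, collapse = "")
  if (length(irreconcilable) > 0L) attr(out, "irreconcilable") <- irreconcilable
  out
}

#' Extract a putative cDNA from exon annotations
#'
#' Concatenates exon substrings in order.  Single-exon annotations are
#' rejected: only multi-exon gene-like structures are carried forward.
#'
#' @param contig Contig sequence.
#' @param exons Data frame with columns `start`, `end` (0-based half-open)
#'   and optionally `type` (`initial`/`internal`/`final`).
#' @return cDNA string.
#' @export
extract_cdna <- function(contig, exons) {
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) < 2L) {
    stop("gene-like structures require more than one exon")
  }
  L <- nchar(contig)
  if (any(exons$start < 0) || any(exons$end > L) ||
      any(exons$end <= exons$start)) {
    stop("exon interval out of contig range")
  }
  if (any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exon intervals overlap")
  }
  paste(substring(contig, exons$start + 1L, exons$end), collapse = "")
}

#' Read exon annotations from a GFF3 file
#'
#' Returns 0-based half-open exon intervals per contig, for use with
#' [extract_cdna()].  Requires the `rtracklayer` package.
#'
#' @param path GFF3 file with exon features.
#' @return Named list (by seqid) of data frames with `start`, `end`, `type`.
#' @export
read_exon_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF requires the rtracklayer package")
  }
  g <- rtracklayer::import(path)
  g <- g[tolower(as.character(g$type)) == "exon"]
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(g)),
                   start = BiocGenerics::start(g) - 1L,  # GFF is 1-based
                   end = BiocGenerics::end(g),
                   type = if (!is.null(g$exon_type)) g$exon_type else NA,
                   stringsAsFactors = FALSE)
  split(df[c("start", "end", "type")], df$seqid)
}

#' Count reads matching each query sequence
#'
#' A read counts toward a query when an ungapped perfect (100% identity)
#' match on either strand spans more than `min_cover` of the shorter of the
#' two lengths (a 75-base read cannot cover 70% of a longer contig, so the
#' threshold is taken on `min(query, read)`).
#'
#' @param queries Named character vector of query sequences (contigs or
#'   cDNAs).
#' @param read_sets Named list of character vectors of read sequences (one
#'   element per RNA-seq sample).
#' @param min_cover Coverage fraction threshold (default 0.7, strict).
#' @return Integer matrix: rows = queries, columns = read sets, plus a
#'   `total` column.
#' @export
match_reads <- function(queries, read_sets, min_cover = 0.7) {
  if (is.character(read_sets)) read_sets <- list(reads = read_sets)
  qn <- names(queries)
  if (is.null(qn)) qn <- paste0("query", seq_along(queries))
  out <- matrix(0L, nrow = length(queries), ncol = length(read_sets),
                dimnames = list(qn, names(read_sets)))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qboth <- paste(c(q, revcomp(q)), collapse = "|")
    for (si in seq_along(read_sets)) {
      reads <- read_sets[[si]]
      cnt <- 0L
      for (r in reads) {
        need <- floor(min_cover * min(nchar(q), nchar(r)) + 1e-9) + 1L
        if (need > nchar(r)) next
        hit <- FALSE
        for (s in seq_len(nchar(r) - need + 1L)) {
          if (grepl(substr(r, s, s + need - 1L), qboth, fixed = TRUE)) {
            hit <- TRUE
            break
          }
        }
        if (hit) cnt <- cnt + 1L
      }
      out[qi, si] <- cnt
    }
  }
  cbind(out, total = as.integer(rowSums(out)))
}
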