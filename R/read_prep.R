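#' Phred quality score to error probability
#'
#' A quality of 20 corresponds to an error probability of 1 in 100 bases.
#'
#' @param q Non-negative integer Phred score(s).
#' @return `10^(-q/10)`, vectorised.
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("Phred score must be non-negative")
  10^(-q / 10)
}

.qual_ints <- function(qualities) utf8ToInt(qualities) - 33L

#' Sliding-window quality trimming of a read
#'
#' Windows of `window` bases are scanned from the 5' end; at the first window
#' whose mean quality falls below `q_threshold` the read is truncated, keeping
#' bases from the window start while their individual quality is still at or
#' above the threshold (the convention of common sliding-window trimmers,
#' which cuts at the actual onset of the low-quality run rather than at the
#' window boundary).  Reads shorter than `min_length` after trimming are
#' dropped.
#'
#' @param sequence Read sequence.
#' @param qualities Phred+33 quality string of the same length.
#' @param window Window size in bases (default 10).  A read shorter than the
#'   window is evaluated as a single window.
#' @param q_threshold Mean-quality threshold (default 20).
#' @param min_length Minimum surviving length (default 70).
#' @return `list(sequence=, qualities=)` or `NULL` when the read is dropped.
#' @export
sliding_window_trim <- function(sequence, qualities, window = 10L,
                                q_threshold = 20L, min_length = 70L) {
  stopifnot(window >= 1L, nchar(sequence) == nchar(qualities))
  q <- .qual_ints(qualities)
  n <- length(q)
  if (n == 0L) return(NULL)
  w <- min(window, n)
  # mean quality of each window starting at 1..n-w+1
  cs <- c(0, cumsum(q))
  starts <- seq_len(n - w + 1L)
  means <- (cs[starts + w] - cs[starts]) / w
  fail <- which(means < q_threshold)
  if (length(fail) == 0L) {
    keep <- n
  } else {
    i <- starts[fail[1L]]
    while (i <= n && q[i] >= q_threshold) i <- i + 1L
    keep <- i - 1L
  }
  if (keep < min_length) return(NULL)
  list(sequence = substr(sequence, 1L, keep),
       qualities = substr(qualities, 1L, keep))
}

#' Remove N bases from a read
#'
#' All `N` characters are deleted (qualities deleted in lockstep when
#' present); the read is dropped when fewer than `min_length` bases remain.
#'
#' @param sequence Read sequence over `{A,C,G,T,N}`.
#' @param qualities Optional Phred+33 quality string.
#' @param min_length Minimum surviving length (default 50).
#' @return `list(sequence=, qualities=)` (`qualities` `NULL` when absent) or
#'   `NULL` when the read is dropped.
#' @export
strip_n <- function(sequence, qualities = NULL, min_length = 50L) {
  keep_seq <- gsub("N", "", sequence, fixed = TRUE)
  if (nchar(keep_seq) < min_length) return(NULL)
  keep_qual <- NULL
  if (!is.null(qualities)) {
    stopifnot(nchar(sequence) == nchar(qualities))
    idx <- which(strsplit(sequence, "")[[1]] != "N")
    keep_qual <- paste(strsplit(qualities, "")[[1]][idx], collapse = "")
  }
  list(sequence = keep_seq, qualities = keep_qual)
}

#' Quality-trim a table of reads
#'
#' Applies [sliding_window_trim()] to every row; when `drop_pairs` is `TRUE`
#' and a `mate`/`pair_id` structure is present, both mates are dropped when
#' either fails.
#'
#' @param reads Data frame with columns `id`, `sequence`, `qualities` and
#'   optionally `pair_id`.
#' @inheritParams sliding_window_trim
#' @param drop_pairs Drop both mates when either mate is dropped.
#' @return Filtered data frame; a `summary` attribute records input, kept and
#'   dropped counts.
#' @export
trim_reads <- function(reads, window = 10L, q_threshold = 20L,
                       min_length = 70L, drop_pairs = TRUE) {
  res <- mapply(sliding_window_trim, reads$sequence, reads$qualities,
                MoreArgs = list(window = window, q_threshold = q_threshold,
                                min_length = min_length),
                SIMPLIFY = FALSE, USE.NAMES = FALSE)
  kept <- !vapply(res, is.null, logical(1))
  if (drop_pairs && "pair_id" %in% names(reads)) {
    bad_pairs <- unique(reads$pair_id[!kept])
    kept <- kept & !(reads$pair_id %in% bad_pairs)
  }
  out <- reads[kept, , drop = FALSE]
  out$sequence <- vapply(res[kept], `[[`, character(1), "sequence")
  out$qualities <- vapply(res[kept], `[[`, character(1), "qualities")
  rownames(out) <- NULL
  attr(out, "summary") <- c(input = nrow(reads), kept = nrow(out),
                            dropped = nrow(reads) - nrow(out))
  out
}

#' N-filter a table of reads
#'
#' Applies [strip_n()] to every row.
#'
#' @inheritParams trim_reads
#' @param min_length Minimum surviving length (default 50).
#' @return Filtered data frame with Ns removed; `summary` attribute as in
#'   [trim_reads()].
#' @export
nfilter_reads <- function(reads, min_length = 50L) {
  has_qual <- "qualities" %in% names(reads)
  res <- lapply(seq_len(nrow(reads)), function(i) {
    strip_n(reads$sequence[i],
            if (has_qual) reads$qualities[i] else NULL,
            min_length = min_length)
  })
  kept <- !vapply(res, is.null, logical(1))
  out <- reads[kept, , drop = FALSE]
  out$sequence <- vapply(res[kept], `[[`, character(1), "sequence")
  if (has_qual) {
    out$qualities <- vapply(res[kept], `[[`, character(1), "qualities")
  }
  rownames(out) <- NULL
  attr(out, "summary") <- c(input = nrow(reads), kept = nrow(out),
                            dropped = nrow(reads) - nrow(out))
  out
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path (Phred+33; gzip transparently supported).
#' @return Data frame with columns `id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame with columns `id`, `sequence`, `qualities`.
#' @param path Output path (`.gz` suffix gives gzip output).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
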