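#' Tandem-repeat scoring parameters
#'
#' The detection thresholds mirror the Tandem Repeat Finder parameterisation
#' used for microsatellite calling: match weight 2, mismatch penalty 7, indel
#' penalty 5, match probability 80, indel probability 10, minimum alignment
#' score 14, maximum period 6.  Detection here is exhaustive per period with
#' ungapped self-alignment scoring, so the probabilistic candidate-selection
#' parameters (`match_probability`, `indel_probability`) and the indel
#' penalty are carried for fidelity of the record but unused; the reporting
#' threshold semantics are identical (a perfect repeat of length `l` and
#' period `p` scores `(l - p) * match_weight`, so the shortest reportable
#' perfect repeat is `p + 7` bases).
#'
#' @param match_weight,mismatch_penalty,indel_penalty,match_probability,indel_probability,min_score,max_period
#'   See description; all positive, `max_period <= 6`.
#' @return A list of class `repeat_params`.
#' @export
repeat_params <- function(match_weight = 2L, mismatch_penalty = 7L,
                          indel_penalty = 5L, match_probability = 80L,
                          indel_probability = 10L, min_score = 14L,
                          max_period = 6L) {
  p <- list(match_weight = as.integer(match_weight),
            mismatch_penalty = as.integer(mismatch_penalty),
            indel_penalty = as.integer(indel_penalty),
            match_probability = as.integer(match_probability),
            indel_probability = as.integer(indel_probability),
            min_score = as.integer(min_score),
            max_period = as.integer(max_period))
  if (any(unlist(p) <= 0L)) stop("all repeat parameters must be positive")
  if (p$max_period > 6L) stop("max_period must be at most 6")
  class(p) <- "repeat_params"
  p
}

#' Score a candidate repeat region at a fixed period
#'
#' Ungapped self-alignment at lag `period`: every position `i` in
#' `[start, end - period)` is compared with position `i + period`, scoring
#' `+match_weight` for a match and `-mismatch_penalty` for a mismatch.  A
#' perfect repeat of length `l` therefore scores exactly
#' `(l - period) * match_weight`.
#'
#' Coordinates are 0-based half-open, as everywhere in this package.
#'
#' @param sequence DNA string.
#' @param start,end 0-based half-open interval with `end - start > period`.
#' @param period Repeat period, 1 to `params$max_period`.
#' @param params A [repeat_params()] object.
#' @return Integer alignment score (may be negative).
#' @export
#' @examples
#' score_repeat_region(strrep("AATGG", 4), 0, 20, 5)  # 30
score_repeat_region <- function(sequence, start, end, period,
                                params = repeat_params()) {
  if (period < 1L || period > params$max_period) {
    stop("period must be between 1 and ", params$max_period)
  }
  if (end - start <= period) stop("end - start must exceed period")
  x <- utf8ToInt(sequence)
  i <- (start + 1L):(end - period)          # 1-based left partners
  eq <- x[i] == x[i + period]
  sum(ifelse(eq, params$match_weight, -params$mismatch_penalty))
}

# per-phase majority consensus motif of a repeat region (0-based half-open);
# ties resolved toward the alphabetically smallest base
.consensus_motif <- function(chars, start, end, period) {
  idx <- (start + 1L):end
  phase <- (idx - start - 1L) %% period
  vapply(0:(period - 1L), function(ph) {
    tab <- table(chars[idx[phase == ph]])
    names(tab)[order(-tab, names(tab))][1L]
  }, character(1)) |> paste(collapse = "")
}

# extract all maximal-scoring repeat intervals for one period.
# v: per-lag-pair score vector; returns matrix of (i, j, score) in v-index
# space, greedily extracting the best interval (ties: smallest end, then
# smallest start) and masking its bases before the next round.
.extract_period <- function(x, p, params) {
  n <- length(x)
  hits <- NULL
  if (n < p + 2L) return(hits)
  eq <- x[seq_len(n - p)] == x[(p + 1L):n]
  v <- ifelse(eq, params$match_weight, -params$mismatch_penalty)
  masked <- rep(FALSE, n)
  repeat {
    # v entry i uses bases i..i+p; invalid when any of those is masked
    csm <- c(0L, cumsum(masked))
    valid <- (csm[(1L:(n - p)) + p + 1L] - csm[1L:(n - p)]) == 0L
    best <- -Inf; bi <- bj <- NA_integer_
    r <- rle(valid)
    pos <- 1L
    for (seg in seq_along(r$lengths)) {
      len <- r$lengths[seg]
      if (r$values[seg]) {
        pref <- 0
        minp <- 0; mini <- 0L
        for (t in seq_len(len)) {
          pref <- pref + v[pos + t - 1L]
          cand <- pref - minp
          if (cand > best) {
            best <- cand
            bi <- pos + mini          # v start index
            bj <- pos + t - 1L        # v end index
          }
          if (pref < minp) { minp <- pref; mini <- t }
        }
      }
      pos <- pos + len
    }
    if (!is.finite(best) || best < params$min_score) break
    hits <- rbind(hits, c(bi, bj, best))
    masked[bi:(bj + p)] <- TRUE
  }
  hits
}

# shared collapsing rule: order by score desc, period asc, start asc, end
# asc; keep greedily if no base overlap with an already kept hit
.collapse_hits <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df <- df[order(-df$score, df$period, df$start, df$end), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    if (any(keep)) {
      k <- df[keep, , drop = FALSE]
      ok <- all(df$end[i] <= k$start | df$start[i] >= k$end)
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$period), , drop = FALSE]
}

.finish_hits <- function(raw, sequence, sequence_id, params) {
  cols <- c("sequence_id", "start", "end", "period", "motif", "family",
            "copies", "score", "percent_match")
  if (is.null(raw) || nrow(raw) == 0L) {
    df <- data.frame(sequence_id = character(0), start = integer(0),
                     end = integer(0), period = integer(0),
                     motif = character(0), family = character(0),
                     copies = numeric(0), score = integer(0),
                     percent_match = numeric(0), stringsAsFactors = FALSE)
    return(df[cols])
  }
  chars <- strsplit(sequence, "")[[1]]
  mw <- params$match_weight; mm <- params$mismatch_penalty
  raw$motif <- vapply(seq_len(nrow(raw)), function(i) {
    .consensus_motif(chars, raw$start[i], raw$end[i], raw$period[i])
  }, character(1))
  raw$family <- canonical_name(raw$motif)
  raw$copies <- round((raw$end - raw$start) / raw$period, 1)
  len <- raw$end - raw$start - raw$period
  matches <- (raw$score + mm * len) / (mw + mm)
  raw$percent_match <- round(100 * matches / len, 1)
  raw$sequence_id <- sequence_id
  rownames(raw) <- NULL
  raw[cols]
}

#' Find microsatellites in a sequence
#'
#' For each period 1..`max_period`, maximal-scoring ungapped self-alignment
#' intervals with score at least `min_score` are extracted (greedy,
#' non-overlapping within a period); overlapping calls across periods are
#' then collapsed, keeping the highest score with ties broken toward the
#' smaller period.  The consensus motif is the per-phase majority base;
#' `family` is its canonical motif-family name.
#'
#' @param sequence N-free DNA string (run [strip_n()] upstream).
#' @param params A [repeat_params()] object.
#' @param sequence_id Identifier copied into the result.
#' @return Data frame with columns `sequence_id`, `start`, `end` (0-based
#'   half-open), `period`, `motif`, `family`, `copies`, `score`,
#'   `percent_match`, sorted by `start`.
#' @export
#' @examples
#' find_tandem_repeats(paste0("ACGTCTGACTGA", strrep("AATGG", 4), "CTGAGTCA"))
find_tandem_repeats <- function(sequence, params = repeat_params(),
                                sequence_id = "seq") {
  .stopifnot_scalar_string(sequence, "sequence")
  if (nchar(sequence) == 0L) {
    return(.finish_hits(NULL, sequence, sequence_id, params))
  }
  if (grepl("N", sequence, fixed = TRUE)) {
    stop("sequence contains N; strip Ns before repeat detection")
  }
  x <- utf8ToInt(sequence)
  out <- NULL
  for (p in seq_len(min(params$max_period, length(x) - 1L))) {
    h <- .extract_period(x, p, params)
    if (!is.null(h)) {
      out <- rbind(out, data.frame(start = as.integer(h[, 1L]) - 1L,
                                   end = as.integer(h[, 2L]) + p,
                                   period = p,
                                   score = as.integer(h[, 3L])))
    }
  }
  out <- .collapse_hits(out)
  .finish_hits(out, sequence, sequence_id, params)
}

#' Find microsatellites in many sequences
#'
#' @param sequences Named character vector (e.g. from [read_fasta()]).
#' @inheritParams find_tandem_repeats
#' @return Row-bound hit table over all sequences.
#' @export
find_repeats_all <- function(sequences, params = repeat_params()) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  do.call(rbind, lapply(seq_along(sequences), function(i) {
    find_tandem_repeats(sequences[[i]], params, ids[i])
  }))
}

#' Brute-force repeat finder (test oracle)
#'
#' Exhaustively enumerates every `(start, end, period)` interval, scores each
#' by ungapped lag-`period` self-comparison computed directly from the
#' character vector, and applies the same greedy extraction and collapsing
#' rules as [find_tandem_repeats()].  Quadratic in sequence length; intended
#' for verification on sequences of at most a few hundred bases.
#'
#' @inheritParams find_tandem_repeats
#' @return Hit table in the same format as [find_tandem_repeats()].
#' @export
brute_force_repeats <- function(sequence, params = repeat_params(),
                                sequence_id = "seq") {
  n <- nchar(sequence)
  if (n > 2000L) stop("brute_force_repeats is a small-scale oracle")
  if (n == 0L) return(.finish_hits(NULL, sequence, sequence_id, params))
  chars <- strsplit(sequence, "")[[1]]
  out <- NULL
  for (p in seq_len(min(params$max_period, n - 1L))) {
    if (n < p + 2L) next
    eq <- chars[seq_len(n - p)] == chars[(p + 1L):n]
    val <- ifelse(eq, params$match_weight, -params$mismatch_penalty)
    pref <- c(0, cumsum(val))
    masked <- rep(FALSE, n)
    repeat {
      m <- length(val)
      # score of every v-interval [i..j]
      S <- outer(pref[-1], pref[-(m + 1L)], "-")  # S[j, i] = sum v[i..j]
      csm <- c(0L, cumsum(masked))
      okbase <- outer(seq_len(m), seq_len(m), function(j, i) {
        i <= j & (csm[j + p + 1L] - csm[i]) == 0L
      })
      S[!okbase] <- -Inf
      best <- max(S)
      if (!is.finite(best) || best < params$min_score) break
      w <- which(S == best, arr.ind = TRUE)
      w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]  # min end, then start
      bj <- w[1L, 1L]; bi <- w[1L, 2L]
      out <- rbind(out, data.frame(start = bi - 1L, end = bj + p,
                                   period = p, score = as.integer(best)))
      masked[bi:(bj + p)] <- TRUE
    }
  }
  # same collapsing rule, restated independently of .collapse_hits
  if (!is.null(out) && nrow(out) > 1L) {
    out <- out[order(-out$score, out$period, out$start, out$end), ,
               drop = FALSE]
    kept <- list()
    for (i in seq_len(nrow(out))) {
      overlaps <- FALSE
      for (k in kept) {
        if (out$start[i] < k[2L] && out$end[i] > k[1L]) { overlaps <- TRUE; break }
      }
      if (!overlaps) kept[[length(kept) + 1L]] <- c(out$start[i], out$end[i],
                                                    i)
    }
    out <- out[vapply(kept, `[`, numeric(1), 3L), , drop = FALSE]
    out <- out[order(out$start, out$period), , drop = FALSE]
  }
  .finish_hits(out, sequence, sequence_id, params)
}

#' Write a repeat hit table to TSV (1-based inclusive coordinates)
#'
#' Internal coordinates are 0-based half-open; the TSV boundary converts to
#' 1-based inclusive `start`/`end`.
#'
#' @param hits Hit table from [find_tandem_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L   # 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a repeat hit table as BED (0-based half-open, per BED convention)
#'
#' @inheritParams write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$sequence_id, chromStart = hits$start,
                    chromEnd = hits$end,
                    name = paste0(hits$family, "x", hits$copies),
                    score = hits$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
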