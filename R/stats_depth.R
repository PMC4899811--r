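#' K-mer family read-depth table
#'
#' Sums read depths of repeat hits by motif family and sample: because all
#' cyclic rotations and cyclical reverse complements of a motif describe the
#' same repeat, their depths are pooled into one row per family, giving each
#' family a single k-mer read-depth value per sample.
#'
#' @param hits Data frame with columns `family`, `sample_id` and `depth`
#'   (per-hit read depth, e.g. from [read_depth()] of the carrying contig).
#' @return Numeric matrix, rows = family names (sorted), columns = sample
#'   ids; absent combinations are 0.
#' @export
family_depth_table <- function(hits) {
  stopifnot(all(c("family", "sample_id", "depth") %in% names(hits)))
  if (nrow(hits) == 0L) {
    return(matrix(numeric(0), 0L, 0L))
  }
  tab <- stats::xtabs(depth ~ family + sample_id, data = hits)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m[order(rownames(m)), , drop = FALSE]
}

#' Motif-class (period) fraction profile
#'
#' Fraction of microsatellite loci in each period class 1-6, either
#' count-weighted (each locus counts once) or depth-weighted (each locus
#' counts its read depth).
#'
#' @param hits Data frame with a `period` column and, for depth weighting, a
#'   `depth` column.
#' @param weighting `"count"` (default) or `"depth"`.
#' @return Named numeric vector of length 6 (periods "1".."6") summing to 1;
#'   attribute `weighting` records the mode.
#' @export
class_fractions <- function(hits, weighting = c("count", "depth")) {
  weighting <- match.arg(weighting)
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("cannot compute class fractions of an empty hit set")
  }
  w <- if (weighting == "depth") hits$depth else rep(1, nrow(hits))
  out <- vapply(1:6, function(p) sum(w[hits$period == p]), numeric(1))
  names(out) <- as.character(1:6)
  out <- out / sum(out)
  attr(out, "weighting") <- weighting
  out
}

#' Fold enrichment of a motif-class fraction over a baseline
#'
#' @param sample_fraction Fraction observed in the sample.
#' @param baseline_fraction Fraction in the baseline (reference genome or
#'   whole-genome sample); must be positive.
#' @return `sample_fraction / baseline_fraction`.
#' @export
fold_enrichment <- function(sample_fraction, baseline_fraction) {
  if (any(baseline_fraction <= 0)) {
    stop("baseline fraction must be positive")
  }
  sample_fraction / baseline_fraction
}

#' Prevalence of a motif family among repeat-bearing items
#'
#' Fraction of items (reads or contigs) carrying at least one hit of the
#' given family, among items carrying at least one hit of any family.
#'
#' @param hits Data frame with columns `sequence_id` (the item) and `family`.
#' @param family Canonical family name (e.g. `"AATGG"`; the telomeric repeat
#'   GGGTTA canonicalises to `"AACCCT"`).
#' @return Fraction in `[0, 1]`; `NA` when no item has any hit.
#' @export
motif_prevalence <- function(hits, family) {
  items <- unique(hits$sequence_id)
  if (length(items) == 0L) return(NA_real_)
  with_fam <- unique(hits$sequence_id[hits$family == family])
  length(with_fam) / length(items)
}
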