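#' @section Motif families:
#' A microsatellite motif is a repeat unit of 1-6 bases over `{A,C,G,T}`.
#' Two motifs describe the same tandem repeat if one is a cyclic rotation of
#' the other, or a cyclic rotation of its reverse complement (the repeat read
#' from the opposite strand).  The equivalence class is called a *motif
#' family*; an N-mer family has at most `2 * N` members, with fewer when the
#' motif has rotational symmetry (e.g. `AT`) or is its own reverse
#' complement.  The family is named by its lexicographically smallest member
#' so that names are stable across samples.
#' @name motif-families
#' @keywords internal
NULL

.check_motif <- function(motif) {
  .stopifnot_scalar_string(motif, "motif")
  n <- nchar(motif)
  if (n < 1L || n > 6L) stop("motif length must be between 1 and 6, got ", n)
  if (grepl("[^ACGT]", motif)) {
    ch <- regmatches(motif, regexpr("[^ACGT]", motif))
    stop("invalid character '", ch, "' in motif '", motif, "'")
  }
  invisible(motif)
}

#' Cyclic rotations of a motif
#'
#' @param motif A 1-6 base string over `{A,C,G,T}`.
#' @return Sorted character vector of all distinct rotations, including
#'   `motif` itself.
#' @export
#' @examples
#' rotations("AACT")  # AACT ACTA CTAA TAAC
rotations <- function(motif) {
  .check_motif(motif)
  n <- nchar(motif)
  r <- vapply(seq_len(n), function(i) {
    paste0(substr(motif, i, n), substr(motif, 1L, i - 1L))
  }, character(1))
  sort(unique(r))
}

#' All members of a motif's family
#'
#' Union of the cyclic rotations of the motif and of its reverse complement.
#'
#' @inheritParams rotations
#' @return Sorted character vector of family members (at most `2 * period`).
#' @export
#' @examples
#' family_members("AACT")  # 8 members
#' family_members("AT")    # AT TA (self reverse complementary)
family_members <- function(motif) {
  .check_motif(motif)
  sort(unique(c(rotations(motif), rotations(revcomp(motif)))))
}

#' Canonical family of a motif
#'
#' @inheritParams rotations
#' @return An object of class `motif_family` with elements `name` (the
#'   lexicographically smallest member), `members` and `period`.
#' @export
#' @examples
#' canonical_family("GTTA")$name  # "AACT"
canonical_family <- function(motif) {
  members <- family_members(motif)
  structure(
    list(name = members[1L], members = members, period = nchar(motif)),
    class = "motif_family"
  )
}

#' Canonical family name of one or more motifs
#'
#' Vectorised convenience form of [canonical_family()] returning just the
#' name.
#'
#' @param motifs Character vector of motifs.
#' @return Character vector of canonical family names.
#' @export
canonical_name <- function(motifs) {
  vapply(motifs, function(m) family_members(m)[1L], character(1),
         USE.NAMES = FALSE)
}

#' @export
print.motif_family <- function(x, ...) {
  cat(sprintf("<motif family %s, period %d, %d members>\n  %s\n",
              x$name, x$period, length(x$members),
              paste(x$members, collapse = " ")))
  invisible(x)
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number concatenation of a
#' shorter motif (`ATAT` is `AT` twice, hence not primitive).  Non-primitive
#' motifs describe the same locus as their primitive root at a different
#' nominal period, so bait design and statistics restrict to primitive
#' families.
#'
#' @inheritParams rotations
#' @return `TRUE` or `FALSE`.
#' @export
is_primitive <- function(motif) {
  .check_motif(motif)
  n <- nchar(motif)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L && strrep(substr(motif, 1L, d), n %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all motif families of a given period
#'
#' Groups all `4^period` strings into families and returns one
#' `motif_family` per equivalence class, sorted by canonical name.
#'
#' @param period Integer 1-6.
#' @param primitive_only Drop families whose canonical motif is a repetition
#'   of a shorter motif (default `FALSE`).
#' @return List of `motif_family` objects.
#' @export
#' @examples
#' length(enumerate_families(1))                         # 2
#' length(enumerate_families(3, primitive_only = TRUE))  # 10
enumerate_families <- function(period, primitive_only = FALSE) {
  if (!is.numeric(period) || length(period) != 1L || period < 1 || period > 6) {
    stop("period must be a single integer between 1 and 6")
  }
  period <- as.integer(period)
  alph <- c("A", "C", "G", "T")
  all_strings <- do.call(paste0, expand.grid(rep(list(alph), period),
                                             stringsAsFactors = FALSE))
  seen <- new.env(parent = emptyenv())
  fams <- list()
  for (s in sort(all_strings)) {
    if (!is.null(seen[[s]])) next
    f <- canonical_family(s)
    for (m in f$members) seen[[m]] <- TRUE
    if (primitive_only && !is_primitive(f$name)) next
    fams[[f$name]] <- f
  }
  fams[order(names(fams))]
}

#' Write a family table to TSV
#'
#' Columns: `family_name`, `period`, `member_count`, `members`
#' (comma-joined).
#'
#' @param families List of `motif_family` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(families, path) {
  df <- data.frame(
    family_name = vapply(families, `[[`, character(1), "name"),
    period = vapply(families, `[[`, integer(1), "period"),
    member_count = vapply(families, function(f) length(f$members), integer(1)),
    members = vapply(families, function(f) paste(f$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
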