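#' Reverse complement of DNA strings
#'
#' Watson-Crick reverse complement. `N` is preserved as `N`; any other
#' character is an error.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("AACT")   # "AGTT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1], regexpr("[^ACGTN]", x[bad][1]))
    stop("invalid character '", ch, "' in DNA sequence")
  }
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# random DNA of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fraction comparison helper used at the 0/1-based I/O boundary
.stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string")
  }
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
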