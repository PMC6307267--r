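# Small sequence helpers shared across modules.

# reverse complement of a plain ACGT(N/IUPAC) character scalar
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complementChar <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAString(x)))
}

# Hamming distance between equal-length character scalars
hammingDist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

gcPercentChar <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' GC content of a DNA sequence
#'
#' @param seq ACGT string (character scalar).
#' @return Percentage of G+C bases, in \[0, 100\].
#' @examples
#' gcContent("ACGT")  # 50
#' @export
gcContent <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a non-empty string")
  if (!grepl("^[ACGT]+$", seq))
    stop("'seq' must contain only A/C/G/T")
  gcPercentChar(seq)
}
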