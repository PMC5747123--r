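#' Normalise an RNA sequence string
#'
#' Upper-cases, maps T to U and validates the alphabet.  All functions in the
#' package expect sequences that have passed through this normalisation;
#' [read_fasta()] applies it on input.
#'
#' @param x character vector of sequences.
#' @return character vector over the alphabet A, C, G, U.
#' @export
normalize_rna <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid residues in sequence(s): ",
         paste(which(bad), collapse = ", "),
         " (alphabet is A/C/G/U, T accepted on input)")
  }
  if (any(nchar(x) == 0)) stop("empty sequence")
  x
}

# integer encoding used by the C++ kernels: A=0 C=1 G=2 U=3
encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
}

#' Read a multi-record FASTA file of RNA sequences
#'
#' DNA input is accepted: T is mapped to U and case is folded.
#'
#' @param path file path.
#' @return a tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, seq = normalize_rna(as.character(set)))
}

#' Write sequences to FASTA
#'
#' @param seqs tibble with columns `id` and `seq`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pairwise sequence identity of two ungapped same-length sequences
#'
#' Positional identity in percent; used by the synthetic family generator.
#' For identity along an alignment path use [pid()].
#'
#' @param a,b sequences of equal length.
#' @return percentage in \[0, 100\].
#' @export
seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}
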