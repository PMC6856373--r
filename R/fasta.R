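#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a named
#' character vector (names are the first whitespace-delimited token of each
#' header; full headers are kept in the `descriptions` attribute).  Sequences
#' are uppercased.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1L)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
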