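# Thin FASTA helpers around Biostrings; sequences travel through the
# package as named character vectors.

#' Read a protein FASTA file
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
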