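# Thin I/O wrappers around the standard format readers/writers.

#' Read genome sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case nucleotide strings.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes named character vector of nucleotide strings.
#' @param path output file path.
#' @export
write_genome_fasta <- function(genomes, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes), path)
  invisible(path)
}

#' Write a data.frame as a tab-separated table
#'
#' @param x data.frame.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
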