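#' Read an isoform FASTA file
#'
#' Isoform identifiers are taken as the first whitespace-delimited token of
#' each header, in `GENE-n` / UniProt `ACC-n` style.
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a tab-separated table
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE)
}

#' Gene id of an isoform id in `GENE-n` style
#' @param isoform_id character vector.
#' @keywords internal
isoform_gene <- function(isoform_id) sub("-[0-9]+$", "", isoform_id)
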