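# Sequence file input/output thin wrappers (Biostrings does the parsing).

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  toupper(out)
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of residue strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
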