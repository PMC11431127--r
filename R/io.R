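#' Read a FASTA file of RNA/DNA sequences, normalised to the RNA alphabet
#'
#' @param path FASTA file (multi-record).
#' @return Named character vector of normalised sequences
#'   (see [normalize_sequence()]).
#' @export
read_rna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))  # id = first token of the header
  stats::setNames(vapply(as.character(x), normalize_sequence, character(1),
                         USE.NAMES = FALSE), ids)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_rna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Write Vienna-style records (id, sequence, dot-bracket) to file
#'
#' @param folds named list of `fold_result` objects; names are ids.
#' @param seqs named character vector of the folded sequences.
#' @param path output path.
#' @export
write_vienna <- function(folds, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(folds)) {
    writeLines(c(paste0(">", id), unname(seqs[id]),
                 sprintf("%s (%g)", folds[[id]]$structure, folds[[id]]$score)),
               con)
  }
  invisible(path)
}
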