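#' Read a nucleotide FASTA file into a named character vector
#'
#' Sequences are uppercased and keyed by the first whitespace-delimited token
#' of each header; record order is preserved.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(set))
  dup <- nms[duplicated(nms)]
  if (length(dup))
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param assembly Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param line_width Fixed sequence line width (default 80) so outputs are
#'   byte-reproducible.
#' @return The path, invisibly.
#' @export
write_fasta <- function(assembly, path, line_width = 80L) {
  if (length(assembly) == 0L) stop("refusing to write an empty assembly", call. = FALSE)
  if (is.null(names(assembly)) || any(names(assembly) == ""))
    stop("all sequences must be named", call. = FALSE)
  set <- Biostrings::DNAStringSet(unlist(assembly))
  names(set) <- names(assembly)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}
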