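#' Read an alignment-block table
#'
#' A thin normalization of aligner tabular output: one row per local
#' alignment block of a query genome against the draft.
#'
#' @param path TSV with header columns \code{query_id, contig, start, end,
#'   identity, length}.
#' @return data.frame with those columns.
#' @export
read_alignment_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(query_id = "character",
                                         contig = "character",
                                         start = "integer", end = "integer",
                                         identity = "numeric",
                                         length = "integer"))
  need <- c("query_id", "contig", "start", "end", "identity", "length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("alignment-block table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$end <= df$start))
    stop("alignment block with end <= start", call. = FALSE)
  df[need]
}

#' Filter alignment blocks on identity and length
#'
#' Keeps blocks with \code{identity >= min_identity} and \code{length >=
#' min_length} (both boundaries inclusive), preserving input order. Blocks
#' failing either bound are spurious mappings and would otherwise dilute the
#' per-column reference consensus.
#'
#' @param blocks data.frame as returned by \code{\link{read_alignment_blocks}}.
#' @param min_identity Minimum alignment identity, default 0.80.
#' @param min_length Minimum block length in nucleotides, default 1000.
#' @return Filtered data.frame.
#' @export
filter_alignment_blocks <- function(blocks, min_identity = 0.80,
                                    min_length = 1000L) {
  keep <- blocks$identity >= min_identity & blocks$length >= min_length
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
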