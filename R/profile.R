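# Error-context profiling: sequence context immediately upstream of detected
# errors, the dominant signal of systematic nanopore miscalls.

#' Upstream k-mer profile of an error list
#'
#' For each error, extracts the k draft bases immediately upstream of the
#' error position and the erroneous nucleotide (the first draft base of an
#' insertion/substitution, or the first missing base of a deletion).
#' "Upstream" is taken on the draft's forward strand as stored. Errors closer
#' than k to their contig start are excluded and counted separately.
#'
#' @param errors Error data.frame.
#' @param draft Named character vector of draft contigs.
#' @param k k-mer size (default 4).
#' @return List with \code{counts} (data.frame error_type, kmer,
#'   erroneous_base, n) and \code{n_excluded}.
#' @export
upstream_kmer_profile <- function(errors, draft, k = 4L) {
  validate_errors(errors)
  if (nrow(errors) == 0L)
    return(list(counts = data.frame(error_type = character(),
                                    kmer = character(),
                                    erroneous_base = character(),
                                    n = integer(), stringsAsFactors = FALSE),
                n_excluded = 0L))
  seqs <- draft[errors$contig]
  ok <- errors$position > k
  err_base <- ifelse(errors$error_type == "deletion",
                     substr(errors$correction_seq, 1L, 1L),
                     substr(errors$draft_seq, 1L, 1L))
  kmer <- substr(seqs, errors$position - k, errors$position - 1L)
  df <- data.frame(error_type = errors$error_type[ok], kmer = kmer[ok],
                   erroneous_base = err_base[ok], stringsAsFactors = FALSE)
  counts <- stats::aggregate(list(n = rep(1L, nrow(df))),
                             df[c("error_type", "kmer", "erroneous_base")],
                             FUN = sum)
  counts <- counts[order(counts$error_type, counts$kmer,
                         counts$erroneous_base), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_excluded = sum(!ok))
}

#' Length distribution of upstream homopolymers
#'
#' For each error, measures the maximal run of one nucleotide ending at the
#' base immediately upstream of the error position (strictly upstream of the
#' site unless \code{include_site} is set), and tabulates run lengths per
#' error type.
#'
#' @param errors Error data.frame.
#' @param draft Named character vector of draft contigs.
#' @param include_site Also extend the run through the error site itself.
#' @return data.frame with columns \code{error_type}, \code{run_length},
#'   \code{n}.
#' @export
homopolymer_length_distribution <- function(errors, draft,
                                            include_site = FALSE) {
  validate_errors(errors)
  lens <- integer(nrow(errors))
  keep <- logical(nrow(errors))
  for (i in seq_len(nrow(errors))) {
    seq <- draft[[errors$contig[i]]]
    anchor <- errors$position[i] - 1L
    if (include_site && errors$error_type[i] != "deletion")
      anchor <- errors$position[i]
    if (anchor < 1L) next
    ctx <- homopolymer_context(seq, anchor)
    lens[i] <- anchor - ctx$start + 1L
    keep[i] <- TRUE
  }
  df <- data.frame(error_type = errors$error_type[keep],
                   run_length = lens[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(error_type = character(), run_length = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  out <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          df[c("error_type", "run_length")], FUN = sum)
  out <- out[order(out$error_type, out$run_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
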