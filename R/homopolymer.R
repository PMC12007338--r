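#' Homopolymer decomposition of a sequence
#'
#' Splits a contig into maximal runs of one nucleotide. Runs are the unit of
#' evidence grouping throughout the workflow: long-read indel errors cluster
#' in homopolymers, and positions within one run are alignment-equivalent for
#' an indel of the run base.
#'
#' @param seq A single nucleotide sequence string.
#' @return A list with per-position vectors \code{run_id}, \code{run_start},
#'   \code{run_end}, \code{run_len} and per-run vectors \code{starts},
#'   \code{ends}, \code{bases}.
#' @export
homopolymer_runs <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L == 0L) stop("empty sequence", call. = FALSE)
  new_run <- c(TRUE, ch[-1L] != ch[-L])
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1L] - 1L, L)
  lens <- ends - starts + 1L
  list(run_id = run_id,
       run_start = starts[run_id],
       run_end = ends[run_id],
       run_len = lens[run_id],
       starts = starts, ends = ends, bases = ch[starts])
}

#' Maximal homopolymer run containing a position
#'
#' @param seq Contig sequence (string) or a precomputed
#'   \code{\link{homopolymer_runs}} result.
#' @param pos 1-based position.
#' @return List with \code{base}, \code{start}, \code{end}, \code{length}.
#' @export
homopolymer_context <- function(seq, pos) {
  runs <- if (is.character(seq)) homopolymer_runs(seq) else seq
  if (pos < 1L || pos > length(runs$run_id))
    stop("position outside contig", call. = FALSE)
  rid <- runs$run_id[pos]
  list(base = runs$bases[rid], start = runs$starts[rid],
       end = runs$ends[rid], length = runs$ends[rid] - runs$starts[rid] + 1L)
}
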