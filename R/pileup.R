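# Internal pileup model
#
# A `pileup` holds, per contig, how every aligned source (a reference-genome
# alignment block or a raw read) relates to the draft:
#   cov    - one row per source: contiguous covered range [start, end]
#   events - one row per alignment difference: type "mismatch" (seq = source
#            base), "ins" (insertion_after: source carries extra `seq` after
#            `pos`), or "del" (deletion_next: source lacks draft bases
#            pos+1 .. pos+len, seq = those draft bases)
#   depth  - integer vector over all draft positions (gap placeholders inside
#            a declared deletion count as covering)
# Indels attach to the draft base immediately preceding the event, matching
# the mpileup convention. All coordinates are 1-based.

EV_TYPES <- c("mismatch", "ins", "del")

new_pileup <- function(draft, contigs, sources) {
  stopifnot(identical(names(contigs), names(draft)))
  for (nm in names(contigs)) {
    ct <- contigs[[nm]]
    L <- nchar(draft[[nm]])
    ct$length <- L
    ev <- ct$events
    if (nrow(ev)) {
      bad <- !(ev$type %in% EV_TYPES)
      if (any(bad)) stop("unknown event type: ", ev$type[which(bad)[1]])
      if (any(ev$pos < 1L | ev$pos > L))
        stop("event position outside contig ", nm)
      if (any(ev$type == "del" & ev$pos + ev$len > L))
        stop("deletion event overruns contig ", nm)
    }
    ct$depth <- depth_from_cov(ct$cov, L)
    contigs[[nm]] <- ct
  }
  structure(list(contigs = contigs, sources = sources), class = "pileup")
}

depth_from_cov <- function(cov, L) {
  d <- integer(L + 1L)
  if (nrow(cov)) {
    add <- tabulate(cov$start, nbins = L)
    sub <- tabulate(cov$end + 1L, nbins = L + 1L)
    d <- cumsum(add - sub[seq_len(L)])
  } else d <- integer(L)
  as.integer(d[seq_len(L)])
}

covering_sources <- function(ct, pos) {
  ct$cov$source[ct$cov$start <= pos & ct$cov$end >= pos]
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d source(s), %d contig(s)\n",
              length(x$sources), length(x$contigs)))
  for (nm in names(x$contigs)) {
    ct <- x$contigs[[nm]]
    cat(sprintf("  %s: length %d, mean depth %.1f, %d difference event(s)\n",
                nm, ct$length, mean(ct$depth), nrow(ct$events)))
  }
  invisible(x)
}

#' Parse an all-positions mpileup text file against a draft assembly
#'
#' Decodes the samtools mpileup base-string dialect ('.'/',' match, ACGT
#' mismatch, '+N<seq>' insertion, '-N<seq>' deletion, '*' gap placeholder,
#' '^X' / '$' segment boundaries). Source identity is assigned positionally
#' and tracked across columns through the segment markers, so each aligned
#' block is one persistent source. Base/mapping quality characters are
#' consumed, never stored.
#'
#' @param path Path to the mpileup text file (every draft position present,
#'   the samtools \code{-aa} contract; depth capping must be disabled
#'   upstream).
#' @param draft Named character vector of draft contigs (see
#'   \code{\link{read_fasta}}).
#' @return A \code{pileup} object.
#' @export
parse_mpileup <- function(path, draft) {
  if (!file.exists(path)) stop("mpileup file not found: ", path, call. = FALSE)
  cols <- scan(path, what = list(chrom = character(), pos = integer(),
                                 ref = character(), depth = integer(),
                                 bases = character(), quals = character()),
               sep = "\t", quote = "", quiet = TRUE, fill = TRUE,
               na.strings = character())
  if (length(cols$chrom) == 0L) stop("empty mpileup file: ", path, call. = FALSE)
  unknown <- setdiff(unique(cols$chrom), names(draft))
  if (length(unknown))
    stop("mpileup contig(s) absent from draft: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  contig_idx <- match(cols$chrom, names(draft))
  draft_base <- substr(draft[contig_idx], cols$pos, cols$pos)
  bad <- which(toupper(cols$ref) != draft_base & toupper(cols$ref) != "N")
  if (length(bad))
    stop(sprintf("mpileup reference base disagrees with draft at %s:%d",
                 cols$chrom[bad[1]], cols$pos[bad[1]]), call. = FALSE)

  dec <- .decode_pileup_cpp(contig_idx, cols$pos, cols$depth, cols$bases)
  cov <- as.data.frame(dec$cov, stringsAsFactors = FALSE)
  ev <- as.data.frame(dec$events, stringsAsFactors = FALSE)
  ev$type <- EV_TYPES[ev$type]

  contigs <- vector("list", length(draft))
  names(contigs) <- names(draft)
  for (i in seq_along(draft)) {
    nm <- names(draft)[i]
    L <- nchar(draft[[nm]])
    seen <- cols$pos[contig_idx == i]
    if (length(seen) == 0L || length(seen) != L)
      stop(sprintf("mpileup does not cover every position of contig %s (%d of %d)",
                   nm, length(seen), L), call. = FALSE)
    ci <- cov[cov$contig == i, c("source", "start", "end")]
    ei <- ev[ev$contig == i, c("source", "pos", "type", "len", "seq")]
    rownames(ci) <- rownames(ei) <- NULL
    contigs[[i]] <- list(cov = ci, events = ei)
  }
  sources <- paste0("S", seq_len(dec$n_sources))
  new_pileup(draft, contigs, sources)
}

#' Serialize a pileup back to all-positions mpileup text
#'
#' Inverse of \code{\link{parse_mpileup}} up to quality placeholders: every
#' draft position is emitted, including zero-coverage columns.
#'
#' @param pileup A \code{pileup} object.
#' @param draft Named character vector of draft contigs.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mpileup <- function(pileup, draft, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(draft)) {
    ct <- pileup$contigs[[nm]]
    ev <- ct$events
    lines <- .encode_pileup_cpp(nm, draft[[nm]],
                                as.integer(ct$cov$source),
                                as.integer(ct$cov$start),
                                as.integer(ct$cov$end),
                                as.integer(ev$source), as.integer(ev$pos),
                                match(ev$type, EV_TYPES), ev$seq)
    writeLines(lines, con)
  }
  invisible(path)
}

empty_events <- function() {
  data.frame(source = integer(), pos = integer(), type = character(),
             len = integer(), seq = character(), stringsAsFactors = FALSE)
}

# Build a pileup directly from per-contig cov/event tables (used by the
# synthetic-world generator and by tests).
pileup_from_tables <- function(draft, cov_by_contig, events_by_contig, n_sources) {
  contigs <- vector("list", length(draft))
  names(contigs) <- names(draft)
  for (nm in names(draft)) {
    cv <- cov_by_contig[[nm]]
    if (is.null(cv)) cv <- data.frame(source = integer(), start = integer(),
                                      end = integer())
    ev <- events_by_contig[[nm]]
    if (is.null(ev)) ev <- empty_events()
    ev <- ev[order(ev$pos, ev$source), , drop = FALSE]
    rownames(ev) <- rownames(cv) <- NULL
    contigs[[nm]] <- list(cov = cv, events = ev)
  }
  new_pileup(draft, contigs, paste0("S", seq_len(n_sources)))
}
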