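# Module two: read-based error adjustment.
#
# Reference-detected candidates are confirmed, relocated, split or removed
# using raw-read pileup evidence, limiting reference bias: an indel candidate
# is kept wherever reads support it (and is never dropped outright), while a
# substitution candidate survives only with read support for a single
# replacement nucleotide.

#' Read ADP profile of a window
#'
#' Computes a per-site read alignment difference probability for one error
#' type and length across a search window. Sites falling in the same draft
#' homopolymer run are grouped into a single representative site (leftmost,
#' per-read deduplicated support), because positions within a run are
#' alignment-equivalent for an indel of the run base; an event that would
#' break a homopolymer (inserting a non-run base) stays a separate site.
#'
#' @param read_pileup Raw-read \code{pileup}.
#' @param draft Named character vector of draft contigs.
#' @param contig Contig name.
#' @param window Integer vector \code{c(start, end)} of anchor positions.
#' @param error_type One of the three error types.
#' @param length Event length in nucleotides (ignored for substitutions).
#' @return data.frame with columns \code{site} (representative anchor),
#'   \code{key}, \code{adp}, \code{n_support}, \code{depth}, \code{top_seq};
#'   zero rows when no read covers the window.
#' @export
read_adp_profile <- function(read_pileup, draft, contig, window, error_type,
                             length = 1L) {
  error_type <- match.arg(error_type, ERROR_TYPES)
  ct <- read_pileup$contigs[[contig]]
  if (is.null(ct)) stop("unknown contig: ", contig, call. = FALSE)
  seq <- draft[[contig]]
  runs <- homopolymer_runs(seq)
  L <- nchar(seq)
  empty <- data.frame(site = integer(), key = character(), adp = numeric(),
                      n_support = integer(), depth = integer(),
                      top_seq = character(), stringsAsFactors = FALSE)

  ev <- ct$events
  if (error_type == "substitution") {
    ev <- ev[ev$type == "mismatch" & ev$seq != "N", , drop = FALSE]
  } else if (error_type == "insertion") {
    ev <- ev[ev$type == "del" & ev$len == length, , drop = FALSE]
  } else {
    ev <- ev[ev$type == "ins" & ev$len == length, , drop = FALSE]
  }
  ev <- ev[ev$pos >= window[1] & ev$pos <= window[2], , drop = FALSE]
  if (error_type == "insertion") ev <- ev[ev$pos < L, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)

  if (error_type == "substitution") {
    key <- sprintf("p%d_%s", ev$pos, ev$seq)
  } else if (error_type == "insertion") {
    key <- sprintf("r%d", runs$run_id[ev$pos + 1L])
  } else {
    key <- delE_group_key(ev, seq, runs, L)
  }

  rows <- lapply(split(seq_len(nrow(ev)), key), function(g) {
    sub <- ev[g, , drop = FALSE]
    site <- min(sub$pos)
    depth <- ct$depth[site]
    n <- base::length(unique(sub$source))
    tb <- sort(table(sub$seq), decreasing = TRUE)
    data.frame(site = site, key = key[g[1L]],
               adp = if (depth > 0L) n / depth else 0,
               n_support = n, depth = depth,
               top_seq = min(names(tb)[tb == max(tb)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Group key for deletion-error (source insertion) events: insertions whose
# first base extends an adjacent draft run share that run; others are unique
# homopolymer-breaking sites.
delE_group_key <- function(ev, seq, runs, L) {
  first <- substr(ev$seq, 1L, 1L)
  base_here <- substr(seq, ev$pos, ev$pos)
  base_next <- substr(seq, ev$pos + 1L, ev$pos + 1L)
  ctx <- ifelse(base_here == first, ev$pos,
                ifelse(ev$pos < L & base_next == first, ev$pos + 1L,
                       NA_integer_))
  ifelse(is.na(ctx), sprintf("b%d_%s", ev$pos, first),
         sprintf("r%d_%s", runs$run_id[ctx], first))
}

# Group key of an existing candidate, in the same keyspace as
# read_adp_profile, so the initial site can be looked up in the profile.
candidate_group_key <- function(candidate, seq, runs, L) {
  if (candidate$error_type == "insertion") {
    sprintf("r%d", runs$run_id[candidate$position])
  } else {
    ev <- data.frame(pos = candidate$position, seq = candidate$correction_seq,
                     stringsAsFactors = FALSE)
    delE_group_key(ev, seq, runs, L)
  }
}

#' Adjust an indel candidate with read evidence
#'
#' The initial reference-detected site is assessed first: read support at or
#' above \code{adjust_threshold_indel} confirms it in place. Otherwise the
#' best-supported same-type, same-length site in the window replaces it
#' (status \code{"adjusted"}); a 2-nt indel without same-length support may be
#' split into two read-supported 1-nt indels (status \code{"split"}). Lacking
#' any support, the candidate is retained unadjusted — indel candidates are
#' never dropped.
#'
#' @param candidate One-row error data.frame (insertion or deletion type).
#' @param read_pileup Raw-read \code{pileup}.
#' @param draft Named character vector of draft contigs.
#' @param config A \code{\link{polish_config}}.
#' @return Error data.frame with one (confirmed/adjusted/retained) or two
#'   (split) rows.
#' @export
adjust_indel <- function(candidate, read_pileup, draft,
                         config = polish_config()) {
  stopifnot(nrow(candidate) == 1L,
            candidate$error_type %in% c("insertion", "deletion"))
  contig <- candidate$contig
  seq <- draft[[contig]]
  L <- nchar(seq)
  if (candidate$position < 1L || candidate$position > L)
    stop("candidate window outside contig ", contig, call. = FALSE)
  runs <- homopolymer_runs(seq)
  half <- (config$adjust_window - 1L) %/% 2L
  win <- c(max(1L, candidate$position - half),
           min(L, candidate$position + half))
  thr <- config$adjust_threshold_indel

  prof <- read_adp_profile(read_pileup, draft, contig, win,
                           candidate$error_type, candidate$length)
  init_key <- candidate_group_key(candidate, seq, runs, L)
  init <- prof[prof$key == init_key, , drop = FALSE]

  if (nrow(init) == 1L && init$adp >= thr) {
    candidate$status <- "confirmed"
    candidate$read_adp <- init$adp
    return(candidate)
  }

  supported <- prof[prof$adp >= thr, , drop = FALSE]
  if (nrow(supported)) {
    pick <- supported[order(-supported$adp, supported$site), ][1L, ]
    out <- candidate
    out$status <- "adjusted"
    out$original_position <- candidate$position
    out$read_adp <- pick$adp
    if (candidate$error_type == "insertion") {
      out$position <- pick$site + 1L
      out$draft_seq <- substr(seq, out$position, out$position + out$length - 1L)
    } else {
      out$position <- pick$site
      out$correction_seq <- pick$top_seq
    }
    return(out)
  }

  if (candidate$length == 2L) {
    prof1 <- read_adp_profile(read_pileup, draft, contig, win,
                              candidate$error_type, 1L)
    sup1 <- prof1[prof1$adp >= thr, , drop = FALSE]
    if (nrow(sup1) >= 2L) {
      sup1 <- sup1[order(-sup1$adp, sup1$site), ][1:2, ]
      sup1 <- sup1[order(sup1$site), ]
      halves <- lapply(seq_len(2L), function(i) {
        h <- candidate
        h$length <- 1L
        h$status <- "split"
        h$original_position <- candidate$position
        h$read_adp <- sup1$adp[i]
        if (candidate$error_type == "insertion") {
          h$position <- sup1$site[i] + 1L
          h$draft_seq <- substr(seq, h$position, h$position)
          h$correction_seq <- ""
        } else {
          h$position <- sup1$site[i]
          h$draft_seq <- ""
          h$correction_seq <- sup1$top_seq[i]
        }
        h
      })
      return(do.call(rbind, halves))
    }
  }

  candidate$status <- "retained_unsupported"
  candidate$read_adp <- if (nrow(init) == 1L) init$adp else 0
  candidate
}

#' Confirm or remove a substitution candidate with read evidence
#'
#' All three alternative nucleotides are assessed at the site from raw,
#' unfiltered reads; the alternative with the greatest read ADP at or above
#' \code{adjust_threshold_sub} becomes the correction (it may differ from the
#' reference-suggested base). Lacking such support, the substitution is
#' removed.
#'
#' @param candidate One-row error data.frame of substitution type.
#' @param read_pileup Raw-read \code{pileup}.
#' @param config A \code{\link{polish_config}}.
#' @return One-row error data.frame, status \code{"confirmed"} or
#'   \code{"removed"}.
#' @export
confirm_substitution <- function(candidate, read_pileup,
                                 config = polish_config()) {
  stopifnot(nrow(candidate) == 1L, candidate$error_type == "substitution")
  ct <- read_pileup$contigs[[candidate$contig]]
  if (is.null(ct)) stop("unknown contig: ", candidate$contig, call. = FALSE)
  pos <- candidate$position
  depth <- ct$depth[pos]
  ev <- ct$events
  ev <- ev[ev$pos == pos & ev$type == "mismatch" &
             ev$seq %in% setdiff(c("A", "C", "G", "T"), candidate$draft_seq), ,
           drop = FALSE]
  if (depth > 0L && nrow(ev)) {
    cnt <- vapply(split(ev$source, ev$seq),
                  function(s) length(unique(s)), integer(1))
    adp <- cnt / depth
    best <- sort(names(adp)[adp == max(adp)])[1L]
    if (adp[[best]] >= config$adjust_threshold_sub) {
      candidate$status <- "confirmed"
      candidate$correction_seq <- best
      candidate$read_adp <- adp[[best]]
      return(candidate)
    }
    candidate$read_adp <- max(adp)
  } else {
    candidate$read_adp <- 0
  }
  candidate$status <- "removed"
  candidate
}

#' Adjust a full candidate list with (optional) read evidence
#'
#' With reads, every indel candidate goes through \code{\link{adjust_indel}}
#' and every substitution through \code{\link{confirm_substitution}};
#' removed substitutions stay in the table (status \code{"removed"}) but are
#' excluded from correction. Without reads, all substitution candidates are
#' dropped — no read can vouch for a single replacement base — and indels
#' pass through with status \code{"retained_unsupported"}.
#'
#' @param candidates Error data.frame from \code{\link{detect_errors}}.
#' @param draft Named character vector of draft contigs.
#' @param read_pileup Raw-read \code{pileup}, or NULL when unavailable.
#' @param config A \code{\link{polish_config}}.
#' @return Finalized error data.frame, sorted by (contig, position, type).
#' @export
adjust_errors <- function(candidates, draft, read_pileup = NULL,
                          config = polish_config()) {
  validate_config(config)
  validate_errors(candidates)
  if (nrow(candidates) == 0L) return(sort_errors(candidates))
  if (is.null(read_pileup)) {
    out <- candidates[candidates$error_type != "substitution", , drop = FALSE]
    if (nrow(out)) out$status <- "retained_unsupported"
    return(sort_errors(out))
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    if (cand$error_type == "substitution")
      confirm_substitution(cand, read_pileup, config)
    else
      adjust_indel(cand, read_pileup, draft, config)
  })
  sort_errors(do.call(rbind, rows))
}
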