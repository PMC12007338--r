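# Module one: reference-comparative candidate error detection.
#
# The draft is scanned column by column against the reference pileup. A
# column triggers when its positional alignment difference probability (ADP)
# reaches `regional_trigger`; the surrounding window (whose size follows the
# multi-pass schedule) is then evaluated regionally, each reference counted
# at most once, and the best homopolymer-weighted site in the window is
# emitted as a candidate error when the reference consensus reaches
# `error_threshold`.

#' Sufficient-coverage gate for a pileup column
#'
#' Detection never emits candidates at columns covered by fewer reference
#' genomes than \code{min_ref_coverage}.
#'
#' @param pileup A \code{pileup} object.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @param min_ref_coverage Minimum covering sources (default 5).
#' @return Logical.
#' @export
coverage_gate <- function(pileup, contig, pos, min_ref_coverage = 5L) {
  ct <- pileup$contigs[[contig]]
  if (is.null(ct)) stop("unknown contig: ", contig, call. = FALSE)
  ct$depth[pos] >= min_ref_coverage
}

#' Positional alignment difference probability at one column
#'
#' The ADP of an error type is the proportion of sources covering the column
#' whose alignment reports the corresponding difference with the draft:
#' mismatches for substitution errors; deletions in the source (the draft
#' carries extra bases) for insertion errors; insertions in the source (the
#' draft is missing bases) for deletion errors. Indel events longer than
#' \code{max_indel_len} are taken as genuine sequence variants and ignored
#' entirely. Mismatching N observations count toward depth but never toward
#' the numerator.
#'
#' @param pileup A \code{pileup} object.
#' @param contig Contig name.
#' @param pos 1-based position (for indels, the anchor base immediately
#'   preceding the event).
#' @param error_type One of \code{"substitution"}, \code{"insertion"},
#'   \code{"deletion"}.
#' @param max_indel_len Longest indel considered (default 2).
#' @return List with \code{adp}, \code{numerator}, \code{depth} and
#'   \code{detail} (per-alternative or per-length support counts).
#' @export
positional_adp <- function(pileup, contig, pos, error_type,
                           max_indel_len = 2L) {
  error_type <- match.arg(error_type, ERROR_TYPES)
  ct <- pileup$contigs[[contig]]
  if (is.null(ct)) stop("unknown contig: ", contig, call. = FALSE)
  depth <- ct$depth[pos]
  ev <- ct$events[ct$events$pos == pos, , drop = FALSE]
  if (error_type == "substitution") {
    ev <- ev[ev$type == "mismatch" & ev$seq != "N", , drop = FALSE]
    detail <- table(ev$seq)
  } else if (error_type == "insertion") {
    ev <- ev[ev$type == "del" & ev$len <= max_indel_len, , drop = FALSE]
    detail <- table(ev$len)
  } else {
    ev <- ev[ev$type == "ins" & ev$len <= max_indel_len, , drop = FALSE]
    detail <- table(ev$len)
  }
  num <- length(unique(ev$source))
  list(adp = if (depth > 0L) num / depth else NA_real_,
       numerator = num, depth = depth, detail = detail)
}

#' Window and strategy schedule for a scan pass
#'
#' Pass 1 is the single trigger column; pass 2 spans the maximal homopolymer
#' run containing the column; the first elective pass (pass 3) uses an 11-nt
#' centred window which then grows by five nucleotides per side each further
#' pass. The two extra search strategies (window shifting and
#' alternative-length merging) are enabled on every second elective pass.
#' Windows truncate at contig ends.
#'
#' @param pass_index Pass number, 1-based.
#' @param draft_seq Contig sequence (string) or a
#'   \code{\link{homopolymer_runs}} result.
#' @param position Trigger column.
#' @param config A \code{\link{polish_config}}.
#' @return List with \code{start}, \code{end}, \code{shift_enabled},
#'   \code{merge_enabled}.
#' @export
window_schedule <- function(pass_index, draft_seq, position, config = polish_config()) {
  if (pass_index < 1L || pass_index > n_passes(config))
    stop("pass index out of range: ", pass_index, call. = FALSE)
  runs <- if (is.character(draft_seq)) homopolymer_runs(draft_seq) else draft_seq
  L <- length(runs$run_id)
  if (pass_index == 1L) {
    start <- end <- position
  } else if (pass_index == 2L) {
    start <- runs$run_start[position]
    end <- runs$run_end[position]
  } else {
    half <- (config$third_pass_window - 1L) %/% 2L +
      config$window_growth * (pass_index - 3L)
    start <- max(1L, position - half)
    end <- min(L, position + half)
  }
  elect <- pass_index - 2L
  enabled <- elect >= 1L && elect %% config$strategy_stride == 0L
  list(start = start, end = end,
       shift_enabled = enabled, merge_enabled = enabled)
}

#' Regional alignment difference probability over a window
#'
#' The numerator counts distinct sources with at least one qualifying
#' difference of the given type anywhere in the window; multiple differences
#' on a single aligned source never inflate the rate. The denominator is the
#' number of sources covering the trigger column (reference blocks may end
#' mid-window, so the trigger column defines the comparison set).
#'
#' @param pileup A \code{pileup} object.
#' @param contig Contig name.
#' @param window Integer vector \code{c(start, end)}.
#' @param error_type One of the three error types.
#' @param trigger_pos Column whose covering sources form the denominator.
#' @param config A \code{\link{polish_config}}.
#' @return List with \code{adp}, \code{sources} (contributing source ids),
#'   \code{numerator}, \code{denominator}.
#' @export
regional_adp <- function(pileup, contig, window, error_type, trigger_pos,
                         config = polish_config()) {
  error_type <- match.arg(error_type, ERROR_TYPES)
  ct <- pileup$contigs[[contig]]
  if (is.null(ct)) stop("unknown contig: ", contig, call. = FALSE)
  regional_adp_ct(ct, window[1], window[2], error_type, trigger_pos,
                  config$max_indel_len)
}

regional_adp_ct <- function(ct, wstart, wend, error_type, trigger_pos, max_len,
                            claimed = NULL) {
  den_sources <- covering_sources(ct, trigger_pos)
  den <- length(den_sources)
  ev <- qualifying_events(ct$events, error_type, max_len)
  ev <- ev[ev$pos >= wstart & ev$pos <= wend, , drop = FALSE]
  if (!is.null(claimed) && nrow(ev))
    ev <- ev[!claimed[ev$pos], , drop = FALSE]
  contrib <- intersect(unique(ev$source), den_sources)
  list(adp = if (den > 0L) length(contrib) / den else NA_real_,
       sources = contrib, numerator = length(contrib), denominator = den)
}

qualifying_events <- function(events, error_type, max_len) {
  if (error_type == "substitution")
    events[events$type == "mismatch" & events$seq != "N", , drop = FALSE]
  else if (error_type == "insertion")
    events[events$type == "del" & events$len <= max_len, , drop = FALSE]
  else
    events[events$type == "ins" & events$len <= max_len, , drop = FALSE]
}

# Score every candidate location of `error_type` inside the window and return
# the best one, or NULL when nothing is scorable. Locations sharing a
# homopolymer context and correction type are merged (per-source
# deduplicated) before scoring; score = support fraction x homopolymer
# length, halved when the implied correction would break a run.
score_region_ct <- function(ct, seq, runs, wstart, wend, error_type, config,
                            merge_lengths = FALSE, claimed = NULL) {
  L <- nchar(seq)
  ev <- qualifying_events(ct$events, error_type, config$max_indel_len)
  ev <- ev[ev$pos >= wstart & ev$pos <= wend, , drop = FALSE]
  if (!is.null(claimed) && nrow(ev))
    ev <- ev[!claimed[ev$pos], , drop = FALSE]
  if (error_type == "insertion")  # anchor must have a following draft base
    ev <- ev[ev$pos < L, , drop = FALSE]
  if (nrow(ev) == 0L) return(NULL)

  key <- character(nrow(ev))
  if (error_type == "substitution") {
    key <- sprintf("r%d", runs$run_id[ev$pos])
  } else if (error_type == "insertion") {
    key <- sprintf("r%d", runs$run_id[ev$pos + 1L])
  } else {
    first <- substr(ev$seq, 1L, 1L)
    base_here <- substr(seq, ev$pos, ev$pos)
    base_next <- substr(seq, ev$pos + 1L, ev$pos + 1L)
    ctx <- ifelse(base_here == first, ev$pos,
                  ifelse(ev$pos < L & base_next == first, ev$pos + 1L, NA_integer_))
    key <- ifelse(is.na(ctx), sprintf("b%d_%s", ev$pos, first),
                  sprintf("r%d_%s", runs$run_id[ctx], first))
  }

  groups <- split(seq_len(nrow(ev)), key)
  best <- NULL
  for (g in groups) {
    rows <- ev[g, , drop = FALSE]
    rep_pos <- min(rows$pos)
    support <- unique(rows$source)
    depth <- ct$depth[rep_pos]
    if (depth == 0L) next
    freq <- length(support) / depth

    if (error_type == "substitution") {
      hp_len <- runs$run_len[rep_pos]
      splits <- runs$run_len[rep_pos] >= 2L &&
        rep_pos > runs$run_start[rep_pos] && rep_pos < runs$run_end[rep_pos]
    } else if (error_type == "insertion") {
      hp_len <- runs$run_len[rep_pos + 1L]
      splits <- FALSE  # removing bases never introduces a run-breaking base
    } else {
      first <- substr(rows$seq[1L], 1L, 1L)
      ctx <- if (substr(seq, rep_pos, rep_pos) == first) rep_pos
             else if (rep_pos < L && substr(seq, rep_pos + 1L, rep_pos + 1L) == first) rep_pos + 1L
             else NA_integer_
      hp_len <- if (is.na(ctx)) 1L else runs$run_len[ctx]
      splits <- is.na(ctx) && rep_pos < L &&
        substr(seq, rep_pos, rep_pos) == substr(seq, rep_pos + 1L, rep_pos + 1L)
    }
    score <- freq * hp_len * if (splits) 0.5 else 1
    if (is.null(best) || score > best$score ||
        (score == best$score && rep_pos < best$rep_pos)) {
      best <- list(score = score, rep_pos = rep_pos, rows = rows,
                   support_frac = freq)
    }
  }
  if (is.null(best)) return(NULL)

  rows <- best$rows[best$rows$pos == best$rep_pos, , drop = FALSE]
  if (nrow(rows) == 0L) rows <- best$rows
  if (error_type == "substitution") {
    alt <- sort(table(rows$seq), decreasing = TRUE)
    alt <- names(alt)[alt == max(alt)]
    correction <- min(alt)
    list(position = best$rep_pos, length = 1L,
         draft_seq = substr(seq, best$rep_pos, best$rep_pos),
         correction_seq = correction, score = best$score,
         support_frac = best$support_frac)
  } else if (error_type == "insertion") {
    lens <- rows$len
    len <- if (merge_lengths && length(unique(lens)) > 1L) 1L else {
      tb <- sort(table(lens), decreasing = TRUE)
      as.integer(min(names(tb)[tb == max(tb)]))
    }
    list(position = best$rep_pos + 1L, length = len,
         draft_seq = substr(seq, best$rep_pos + 1L, best$rep_pos + len),
         correction_seq = "", score = best$score,
         support_frac = best$support_frac)
  } else {
    if (merge_lengths && length(unique(rows$len)) > 1L) {
      fb <- sort(table(substr(rows$seq, 1L, 1L)), decreasing = TRUE)
      correction <- min(names(fb)[fb == max(fb)])
    } else {
      tb <- sort(table(rows$seq), decreasing = TRUE)
      correction <- min(names(tb)[tb == max(tb)])
    }
    list(position = best$rep_pos, length = nchar(correction),
         draft_seq = "", correction_seq = correction, score = best$score,
         support_frac = best$support_frac)
  }
}

#' Score a window and choose its candidate error site
#'
#' @param pileup A \code{pileup} object.
#' @param draft Named character vector of contigs.
#' @param contig Contig name.
#' @param window Integer vector \code{c(start, end)}.
#' @param error_type One of the three error types.
#' @param config A \code{\link{polish_config}}.
#' @param merge_lengths Treat disagreeing indel lengths as one shorter event.
#' @return List describing the max-scoring site (position, length, draft_seq,
#'   correction_seq, score, support_frac), or NULL when nothing is scorable.
#' @export
score_region <- function(pileup, draft, contig, window, error_type,
                         config = polish_config(), merge_lengths = FALSE) {
  error_type <- match.arg(error_type, ERROR_TYPES)
  ct <- pileup$contigs[[contig]]
  seq <- draft[[contig]]
  score_region_ct(ct, seq, homopolymer_runs(seq), window[1], window[2],
                  error_type, config, merge_lengths)
}

# Per-position support counts for the scan triggers, vectorized over a contig.
contig_trigger_tallies <- function(ct, L, max_len) {
  ev <- ct$events
  mis <- ev[ev$type == "mismatch" & ev$seq != "N", , drop = FALSE]
  del <- ev[ev$type == "del" & ev$len <= max_len, , drop = FALSE]
  ins <- ev[ev$type == "ins" & ev$len <= max_len, , drop = FALSE]
  cnt <- function(pos) tabulate(pos, nbins = L)
  per_len <- function(df) lapply(seq_len(max_len), function(l) cnt(df$pos[df$len == l]))
  list(sub = cnt(mis$pos), insE = per_len(del), delE = per_len(ins))
}

detect_contig <- function(ct, contig, seq, config, claimed = NULL,
                          eligible = NULL) {
  L <- nchar(seq)
  if (ct$length != L)
    stop("pileup/draft length mismatch for contig ", contig, call. = FALSE)
  runs <- homopolymer_runs(seq)
  draft_ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  depth <- ct$depth
  tal <- contig_trigger_tallies(ct, L, config$max_indel_len)
  if (is.null(claimed)) claimed <- logical(L)
  if (is.null(eligible)) eligible <- rep(TRUE, L)

  insE_max <- Reduce(pmax, tal$insE)
  delE_max <- Reduce(pmax, tal$delE)
  insE_sum <- Reduce(`+`, tal$insE)
  delE_sum <- Reduce(`+`, tal$delE)

  gate <- eligible & depth >= config$min_ref_coverage & draft_ch != "N"
  rows <- list()

  for (p in seq_len(n_passes(config))) {
    elect <- p - 2L
    strat <- elect >= 1L && elect %% config$strategy_stride == 0L
    cnt_ins <- if (strat) insE_sum else insE_max
    cnt_del <- if (strat) delE_sum else delE_max
    trig_cnt <- pmax(tal$sub, cnt_ins, cnt_del)
    trig <- which(gate & !claimed & trig_cnt >= config$regional_trigger * depth)

    for (pos in trig) {
      if (claimed[pos]) next
      win <- window_schedule(p, runs, pos, config)
      type_cnt <- c(substitution = tal$sub[pos], insertion = cnt_ins[pos],
                    deletion = cnt_del[pos])
      for (type in ERROR_TYPES) {
        if (type_cnt[[type]] < config$regional_trigger * depth[pos]) next
        wins <- list(c(win$start, win$end))
        if (win$shift_enabled) {
          w <- win$end - win$start
          wins <- c(wins, list(c(max(1L, pos - w), pos)),
                    list(c(pos, min(L, pos + w))))
        }
        best_reg <- -1; best_w <- wins[[1]]
        for (w in wins) {
          reg <- regional_adp_ct(ct, w[1], w[2], type, pos,
                                 config$max_indel_len, claimed)$adp
          if (!is.na(reg) && reg > best_reg) { best_reg <- reg; best_w <- w }
        }
        if (is.na(best_reg) || best_reg < config$error_threshold) next
        site <- score_region_ct(ct, seq, runs, best_w[1], best_w[2], type,
                                config, merge_lengths = win$merge_enabled,
                                claimed = claimed)
        if (is.null(site) || site$support_frac < config$error_threshold) next
        rows[[length(rows) + 1L]] <- new_error_df(
          contig = contig, position = site$position, error_type = type,
          length = site$length, draft_seq = site$draft_seq,
          correction_seq = site$correction_seq,
          reference_adp = site$support_frac, regional_adp = best_reg,
          score = site$score, read_adp = NA_real_, status = "detected",
          original_position = site$position, pass_found = p)
        claimed[best_w[1]:best_w[2]] <- TRUE
      }
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else new_error_df()
  list(candidates = cand, claimed = claimed)
}

#' Detect candidate errors from a reference pileup
#'
#' Runs the multi-pass windowed scan over every contig. A candidate is
#' emitted when (i) the trigger column's positional ADP reaches
#' \code{regional_trigger}, (ii) the regional ADP of the error type over the
#' pass window reaches \code{error_threshold}, and (iii) the best-scoring
#' merged site's own deduplicated reference support reaches
#' \code{error_threshold} — i.e., the covering references report the same
#' alignment difference. Columns inside an emitted candidate's window are
#' claimed and skipped in later passes. When a secondary pileup is supplied,
#' columns failing the primary coverage gate are re-evaluated against it with
#' identical logic, supplementing detection in low-coverage regions.
#'
#' @param ref_pileup Reference-genome \code{pileup}.
#' @param draft Named character vector of draft contigs.
#' @param config A \code{\link{polish_config}}.
#' @param secondary_pileup Optional second reference-set \code{pileup}.
#' @return Error data.frame of candidates with status \code{"detected"},
#'   sorted by (contig, position, type).
#' @export
detect_errors <- function(ref_pileup, draft, config = polish_config(),
                          secondary_pileup = NULL) {
  validate_config(config)
  out <- list()
  for (contig in names(draft)) {
    ct <- ref_pileup$contigs[[contig]]
    if (is.null(ct))
      stop("reference pileup lacks contig ", contig, call. = FALSE)
    res <- detect_contig(ct, contig, draft[[contig]], config)
    cand <- res$candidates
    if (!is.null(secondary_pileup)) {
      ct2 <- secondary_pileup$contigs[[contig]]
      if (is.null(ct2))
        stop("secondary pileup lacks contig ", contig, call. = FALSE)
      low <- ct$depth < config$min_ref_coverage
      res2 <- detect_contig(ct2, contig, draft[[contig]], config,
                            claimed = res$claimed, eligible = low)
      extra <- res2$candidates
      if (nrow(extra)) {
        dup <- paste(extra$position, extra$error_type) %in%
          paste(cand$position, cand$error_type)
        cand <- rbind(cand, extra[!dup, , drop = FALSE])
      }
    }
    out[[contig]] <- cand
  }
  sort_errors(do.call(rbind, out))
}
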