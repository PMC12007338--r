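# Seeded synthetic test worlds: a truth genome, an error-injected draft,
# independently divergent reference genomes, and simulated raw reads — with
# every alignment expressed exactly from the known edit coordinates (no
# heuristic aligner) and serializable as FASTA + all-positions mpileup.
#
# The generator emulates the error regime of nanopore draft assemblies:
# injected errors are dominated by 1-2 nt homopolymer-associated deletions,
# and the read error model escalates indel rates with homopolymer length.

#' Default injected-error mix
#'
#' Fifty errors dominated by homopolymer-associated 1-2 nt deletions, plus
#' spurious insertions and substitutions — the profile typical of nanopore
#' draft assemblies.
#'
#' @return data.frame with columns \code{type}, \code{length},
#'   \code{placement} (\code{random}, \code{after_kmer},
#'   \code{in_homopolymer}), \code{motif}, \code{min_run}, \code{n}.
#' @export
error_mix <- function() {
  data.frame(
    type = c("substitution", "deletion", "deletion", "deletion",
             "insertion", "insertion"),
    length = c(1L, 1L, 1L, 2L, 1L, 2L),
    placement = c("random", "in_homopolymer", "random", "random",
                  "in_homopolymer", "random"),
    motif = NA_character_,
    min_run = c(NA, 3L, NA, NA, 3L, NA),
    n = c(10L, 15L, 5L, 5L, 10L, 5L),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic world
#'
#' @param genome_length Truth genome length in nucleotides.
#' @param gc_content Fraction of G+C in the truth genome.
#' @param n_references Number of primary reference genomes.
#' @param ref_sub_rate,ref_indel_rate Per-site strain-divergence rates,
#'   drawn independently per reference.
#' @param errors Injected-error table (see \code{\link{error_mix}}).
#' @param min_spacing Minimum distance between injected errors (kept at
#'   least one detection window apart by default).
#' @param margin Error-free zone at contig ends.
#' @param read_depth Fold coverage of simulated reads.
#' @param read_length Read length in nucleotides.
#' @param read_sub_rate Per-base read substitution rate.
#' @param read_indel_rate Per-base read indel rate, multiplied by the
#'   homopolymer run length at the position (length-dependent escalation).
#' @param uncovered_region Optional \code{c(start, end)} draft interval where
#'   no primary reference aligns.
#' @param n_secondary Number of secondary (supplementary) reference genomes;
#'   these always cover the whole draft.
#' @param secondary_sub_rate,secondary_indel_rate Divergence rates of the
#'   secondary set.
#' @param contig_name Name of the single simulated contig.
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @return List of class \code{sim_spec}.
#' @export
simulation_spec <- function(genome_length = 100000L, gc_content = 0.5,
                            n_references = 10L,
                            ref_sub_rate = 0, ref_indel_rate = 0,
                            errors = error_mix(),
                            min_spacing = 60L, margin = 150L,
                            read_depth = 30, read_length = 6000L,
                            read_sub_rate = 0.01, read_indel_rate = 0.002,
                            uncovered_region = NULL,
                            n_secondary = 0L,
                            secondary_sub_rate = ref_sub_rate,
                            secondary_indel_rate = ref_indel_rate,
                            contig_name = "contig_1",
                            seed = 1L) {
  rates <- c(ref_sub_rate, ref_indel_rate, read_sub_rate, read_indel_rate,
             secondary_sub_rate, secondary_indel_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)", call. = FALSE)
  if (genome_length < 1000L) stop("genome_length too small", call. = FALSE)
  if (n_references < 1L) stop("need at least one reference", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_references = as.integer(n_references),
                 ref_sub_rate = ref_sub_rate, ref_indel_rate = ref_indel_rate,
                 errors = errors, min_spacing = as.integer(min_spacing),
                 margin = as.integer(margin), read_depth = read_depth,
                 read_length = as.integer(read_length),
                 read_sub_rate = read_sub_rate,
                 read_indel_rate = read_indel_rate,
                 uncovered_region = uncovered_region,
                 n_secondary = as.integer(n_secondary),
                 secondary_sub_rate = secondary_sub_rate,
                 secondary_indel_rate = secondary_indel_rate,
                 contig_name = contig_name, seed = as.integer(seed)),
            class = "sim_spec")
}

random_genome <- function(L, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

# Apply difference events (relative to `seq`) and return the edited string:
# mismatch replaces the base, "ins" inserts seq after pos, "del" removes the
# next len bases. Single pass over sorted events, O(L + n_events).
apply_edit_events <- function(seq, events) {
  if (nrow(events) == 0L) return(seq)
  events <- events[order(events$pos), , drop = FALSE]
  pieces <- character(2L * nrow(events) + 1L)
  cur <- 1L
  k <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    if (events$type[i] == "mismatch") {
      pieces[k + 1L] <- substr(seq, cur, p - 1L)
      pieces[k + 2L] <- events$seq[i]
      cur <- p + 1L
    } else if (events$type[i] == "ins") {
      pieces[k + 1L] <- substr(seq, cur, p)
      pieces[k + 2L] <- events$seq[i]
      cur <- p + 1L
    } else {
      pieces[k + 1L] <- substr(seq, cur, p)
      pieces[k + 2L] <- ""
      cur <- p + events$len[i] + 1L
    }
    k <- k + 2L
  }
  pieces[k + 1L] <- substr(seq, cur, nchar(seq))
  paste(pieces, collapse = "")
}

#' Inject known errors into a truth genome
#'
#' Produces a draft (truth plus errors) and the ground-truth error list in
#' the corrector's schema, using original-draft coordinates, so that
#' \code{apply_errors(draft, truth_errors)} restores the truth exactly.
#' Injected sites are left-aligned (an indel inside a homopolymer is anchored
#' at the run start) and kept at least \code{min_spacing} apart.
#'
#' @param truth Truth genome string.
#' @param error_spec data.frame as from \code{\link{error_mix}}.
#' @param seed Optional integer seed (NULL inherits the caller's RNG state).
#' @param min_spacing Minimum distance between injected sites.
#' @param margin Error-free zone at contig ends.
#' @param contig_name Contig name recorded in the error list.
#' @return List with \code{draft} and \code{truth_errors}.
#' @export
inject_errors <- function(truth, error_spec, seed = NULL, min_spacing = 60L,
                          margin = 150L, contig_name = "contig_1") {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(truth)
  runs <- homopolymer_runs(truth)
  ch <- strsplit(truth, "", fixed = TRUE)[[1]]
  taken <- integer(0)

  pick_pos <- function(row) {
    lo <- margin; hi <- L - margin
    for (try in seq_len(500L)) {
      if (row$placement == "random") {
        t0 <- sample(lo:hi, 1L)
      } else if (row$placement == "after_kmer") {
        hits <- gregexpr(row$motif, truth, fixed = TRUE)[[1]]
        hits <- hits[hits >= lo & hits + nchar(row$motif) <= hi]
        if (length(hits) == 0L || hits[1] == -1L)
          stop("placement rule unsatisfiable: no occurrence of motif ",
               row$motif, call. = FALSE)
        t0 <- sample(hits, 1L) + nchar(row$motif)
      } else {
        ok <- which(runs$ends - runs$starts + 1L >= row$min_run &
                      runs$starts >= lo & runs$ends <= hi)
        if (length(ok) == 0L)
          stop("placement rule unsatisfiable: no homopolymer of length >= ",
               row$min_run, call. = FALSE)
        t0 <- runs$starts[sample(ok, 1L)]
      }
      if (all(abs(taken - t0) >= min_spacing)) return(t0)
    }
    stop("placement rules unsatisfiable: could not respect spacing ",
         min_spacing, " (overcrowded error spec)", call. = FALSE)
  }

  rows <- error_spec[rep(seq_len(nrow(error_spec)), error_spec$n), , drop = FALSE]
  edits <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    t0 <- pick_pos(row)
    taken <- c(taken, t0)
    if (row$type == "substitution") {
      newb <- sample(other_bases(ch[t0]), 1L)
      edits[[i]] <- list(kind = "sub", t = t0, len = 1L, seq = newb)
    } else if (row$type == "deletion") {
      # draft will be missing truth bases [t, t+len-1]; left-align
      t <- t0
      k <- row$length
      while (t > margin && ch[t - 1L] == ch[t + k - 1L]) t <- t - 1L
      edits[[i]] <- list(kind = "del", t = t, len = k,
                         seq = substr(truth, t, t + k - 1L))
    } else {
      # draft will carry extra bases inserted after truth position t
      k <- row$length
      if (row$placement == "in_homopolymer") {
        t <- runs$starts[runs$run_id[t0]] - 1L
        s <- strrep(ch[t0], k)
      } else {
        t <- t0
        repeat {
          s <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
          if (substr(s, k, k) != ch[t] && substr(s, 1L, 1L) != ch[t + 1L]) break
        }
      }
      edits[[i]] <- list(kind = "ins", t = t, len = k, seq = s)
    }
  }

  ord <- order(vapply(edits, `[[`, integer(1), "t"))
  edits <- edits[ord]
  off <- 0L
  pieces <- character(0)
  cur <- 1L
  recs <- vector("list", length(edits))
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    if (e$kind == "sub") {
      pieces <- c(pieces, substr(truth, cur, e$t - 1L), e$seq)
      cur <- e$t + 1L
      recs[[i]] <- new_error_df(contig = contig_name, position = e$t + off,
                                error_type = "substitution", length = 1L,
                                draft_seq = e$seq,
                                correction_seq = substr(truth, e$t, e$t),
                                reference_adp = NA_real_,
                                regional_adp = NA_real_, score = NA_real_,
                                read_adp = NA_real_, status = "detected",
                                original_position = e$t + off)
    } else if (e$kind == "del") {
      pieces <- c(pieces, substr(truth, cur, e$t - 1L))
      cur <- e$t + e$len
      recs[[i]] <- new_error_df(contig = contig_name,
                                position = e$t - 1L + off,
                                error_type = "deletion", length = e$len,
                                draft_seq = "", correction_seq = e$seq,
                                reference_adp = NA_real_,
                                regional_adp = NA_real_, score = NA_real_,
                                read_adp = NA_real_, status = "detected",
                                original_position = e$t - 1L + off)
      off <- off - e$len
    } else {
      pieces <- c(pieces, substr(truth, cur, e$t), e$seq)
      cur <- e$t + 1L
      recs[[i]] <- new_error_df(contig = contig_name, position = e$t + off + 1L,
                                error_type = "insertion", length = e$len,
                                draft_seq = e$seq, correction_seq = "",
                                reference_adp = NA_real_,
                                regional_adp = NA_real_, score = NA_real_,
                                read_adp = NA_real_, status = "detected",
                                original_position = e$t + off + 1L)
      off <- off + e$len
    }
  }
  pieces <- c(pieces, substr(truth, cur, L))
  draft <- paste(pieces, collapse = "")
  list(draft = draft, truth_errors = sort_errors(do.call(rbind, recs)))
}

# Truth-supporting pileup events (relative to the draft) that any sequence
# derived from the truth exhibits at the injected error sites.
support_events <- function(truth_errors, draft) {
  n <- nrow(truth_errors)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e <- truth_errors[i, ]
    if (e$error_type == "substitution") {
      out[[i]] <- data.frame(pos = e$position, type = "mismatch", len = 1L,
                             seq = e$correction_seq, stringsAsFactors = FALSE)
    } else if (e$error_type == "insertion") {
      out[[i]] <- data.frame(pos = e$position - 1L, type = "del",
                             len = e$length,
                             seq = substr(draft[[e$contig]], e$position,
                                          e$position + e$length - 1L),
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(pos = e$position, type = "ins", len = e$length,
                             seq = e$correction_seq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# A deletion event shadows the next `len` positions with gap placeholders;
# a source cannot report another event inside that shadow.
drop_shadowed <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  ev <- ev[order(ev$pos), , drop = FALSE]
  dels <- which(ev$type == "del")
  if (length(dels) == 0L) return(ev)
  bad <- logical(nrow(ev))
  for (d in dels) {
    if (bad[d]) next
    bad <- bad | (seq_len(nrow(ev)) != d & ev$pos > ev$pos[d] &
                    ev$pos <= ev$pos[d] + ev$len[d])
  }
  ev[!bad, , drop = FALSE]
}

# Independent per-source divergence events over the draft, avoiding forbidden
# zones around injected sites and at most one event per position.
divergence_events <- function(L, sub_rate, indel_rate, forbidden, draft_ch) {
  ev <- list()
  if (sub_rate > 0) {
    pos <- which(stats::runif(L) < sub_rate)
    pos <- pos[!forbidden[pos]]
    if (length(pos)) {
      alt <- vapply(draft_ch[pos], function(b) sample(other_bases(b), 1L), "")
      ev[[length(ev) + 1L]] <- data.frame(pos = pos, type = "mismatch",
                                          len = 1L, seq = alt,
                                          stringsAsFactors = FALSE)
    }
  }
  if (indel_rate > 0) {
    pos <- which(stats::runif(L) < indel_rate)
    pos <- pos[!forbidden[pos] & pos > 3L & pos < L - 3L]
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) > 3L)]
    if (length(pos)) {
      is_ins <- stats::runif(length(pos)) < 0.5
      len <- sample(1:2, length(pos), replace = TRUE, prob = c(0.8, 0.2))
      seqs <- character(length(pos))
      for (j in seq_along(pos)) {
        seqs[j] <- if (is_ins[j])
          paste(sample(c("A", "C", "G", "T"), len[j], replace = TRUE),
                collapse = "")
        else
          paste(draft_ch[(pos[j] + 1L):(pos[j] + len[j])], collapse = "")
      }
      ev[[length(ev) + 1L]] <- data.frame(pos = pos,
                                          type = ifelse(is_ins, "ins", "del"),
                                          len = len, seq = seqs,
                                          stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0L) return(empty_events()[c("pos", "type", "len", "seq")])
  ev <- do.call(rbind, ev)
  ev <- ev[!duplicated(ev$pos), , drop = FALSE]
  drop_shadowed(ev[order(ev$pos), , drop = FALSE])
}

#' Generate a complete synthetic world
#'
#' Builds the truth genome, error-injected draft, divergent reference
#' genomes, and simulated raw reads; expresses every reference/read alignment
#' to the draft exactly from the known edit coordinates; and (optionally)
#' serializes everything to FASTA, mpileup and TSV under \code{dir}.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param dir Optional output directory (created if needed). When NULL, only
#'   in-memory objects are returned.
#' @return List with \code{truth}, \code{draft}, \code{references},
#'   \code{secondary_references}, \code{reads}, \code{truth_errors},
#'   \code{ref_pileup}, \code{read_pileup}, \code{secondary_pileup} and, when
#'   \code{dir} is given, a \code{paths} list.
#' @export
simulate_world <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  nm <- spec$contig_name
  truth <- random_genome(spec$genome_length, spec$gc_content)
  inj <- inject_errors(truth, spec$errors, seed = NULL,
                       min_spacing = spec$min_spacing, margin = spec$margin,
                       contig_name = nm)
  draft <- structure(inj$draft, names = nm)
  te <- inj$truth_errors
  L <- nchar(draft[[nm]])
  draft_ch <- strsplit(draft[[nm]], "", fixed = TRUE)[[1]]
  runs <- homopolymer_runs(draft[[nm]])

  forbidden <- logical(L)
  for (i in seq_len(nrow(te))) {
    lo <- max(1L, te$position[i] - 6L)
    hi <- min(L, te$position[i] + te$length[i] + 6L)
    forbidden[lo:hi] <- TRUE
  }
  supp <- support_events(te, draft)

  build_ref_set <- function(n_refs, sub_rate, indel_rate, uncovered,
                            first_source, name_prefix) {
    cov <- list(); evs <- list(); seqs <- character(n_refs)
    src <- first_source
    for (r in seq_len(n_refs)) {
      div <- divergence_events(L, sub_rate, indel_rate, forbidden, draft_ch)
      allev <- rbind(supp[c("pos", "type", "len", "seq")], div)
      allev <- allev[order(allev$pos), , drop = FALSE]
      seqs[r] <- apply_edit_events(draft[[nm]], allev)
      blocks <- if (is.null(uncovered)) list(c(1L, L)) else {
        b <- list()
        if (uncovered[1] > 1L) b <- c(b, list(c(1L, uncovered[1] - 1L)))
        if (uncovered[2] < L) b <- c(b, list(c(uncovered[2] + 1L, L)))
        b
      }
      for (b in blocks) {
        keep <- allev$pos >= b[1] & allev$pos <= b[2] &
          !(allev$type == "del" & allev$pos + allev$len > b[2])
        bev <- allev[keep, , drop = FALSE]
        cov[[length(cov) + 1L]] <- data.frame(source = src, start = b[1],
                                              end = b[2])
        if (nrow(bev))
          evs[[length(evs) + 1L]] <- data.frame(source = src, bev,
                                                stringsAsFactors = FALSE)
        src <- src + 1L
      }
    }
    names(seqs) <- paste0(name_prefix, seq_len(n_refs))
    list(cov = do.call(rbind, cov),
         events = if (length(evs)) do.call(rbind, evs) else
           empty_events()[c("source", "pos", "type", "len", "seq")],
         seqs = seqs, next_source = src)
  }

  prim <- build_ref_set(spec$n_references, spec$ref_sub_rate,
                        spec$ref_indel_rate, spec$uncovered_region, 1L, "ref")
  ref_pileup <- pileup_from_tables(draft, stats::setNames(list(prim$cov), nm),
                                   stats::setNames(list(prim$events), nm),
                                   prim$next_source - 1L)
  secondary_pileup <- NULL
  sec <- NULL
  if (spec$n_secondary > 0L) {
    sec <- build_ref_set(spec$n_secondary, spec$secondary_sub_rate,
                         spec$secondary_indel_rate, NULL, 1L, "secref")
    secondary_pileup <- pileup_from_tables(
      draft, stats::setNames(list(sec$cov), nm),
      stats::setNames(list(sec$events), nm), sec$next_source - 1L)
  }

  # --- reads ---
  n_reads <- ceiling(spec$read_depth * L / spec$read_length)
  starts <- sample.int(L + spec$read_length - 1L, n_reads, replace = TRUE) -
    spec$read_length + 1L
  ends <- pmin(L, starts + spec$read_length - 1L)
  starts <- pmax(1L, starts)
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  hp_rate <- pmin(spec$read_indel_rate * runs$run_len, 0.4)

  rcov <- data.frame(source = seq_len(n_reads), start = starts, end = ends)
  revs <- vector("list", n_reads)
  rseqs <- character(n_reads)
  for (r in seq_len(n_reads)) {
    s <- starts[r]; e <- ends[r]
    keep <- te$position > s & te$position < e &
      !(te$error_type == "insertion" &
          (te$position - 1L < s | te$position + te$length - 1L > e))
    sev <- supp[keep, , drop = FALSE]
    span <- s:e
    err_pos <- span[stats::runif(length(span)) < spec$read_sub_rate]
    ind_pos <- span[stats::runif(length(span)) < hp_rate[span]]
    ev <- sev
    if (length(err_pos)) {
      err_pos <- err_pos[!forbidden[err_pos]]
      if (length(err_pos)) {
        alt <- vapply(draft_ch[err_pos], function(b) sample(other_bases(b), 1L), "")
        ev <- rbind(ev, data.frame(pos = err_pos, type = "mismatch", len = 1L,
                                   seq = alt, stringsAsFactors = FALSE))
      }
    }
    if (length(ind_pos)) {
      ind_pos <- ind_pos[!forbidden[ind_pos] & ind_pos < e - 2L & ind_pos > s]
      if (length(ind_pos)) {
        is_ins <- stats::runif(length(ind_pos)) < 0.5
        ev <- rbind(ev, data.frame(
          pos = ind_pos, type = ifelse(is_ins, "ins", "del"), len = 1L,
          seq = ifelse(is_ins, draft_ch[ind_pos], draft_ch[ind_pos + 1L]),
          stringsAsFactors = FALSE))
      }
    }
    ev <- ev[!duplicated(ev$pos), , drop = FALSE]
    ev <- drop_shadowed(ev[order(ev$pos), , drop = FALSE])
    revs[[r]] <- if (nrow(ev)) data.frame(source = r, ev,
                                          stringsAsFactors = FALSE) else NULL
    local_ev <- ev
    local_ev$pos <- local_ev$pos - s + 1L
    rseqs[r] <- apply_edit_events(substr(draft[[nm]], s, e), local_ev)
  }
  read_events <- do.call(rbind, revs)
  if (is.null(read_events))
    read_events <- empty_events()[c("source", "pos", "type", "len", "seq")]
  read_pileup <- pileup_from_tables(draft, stats::setNames(list(rcov), nm),
                                    stats::setNames(list(read_events), nm),
                                    n_reads)
  names(rseqs) <- sprintf("read%05d", seq_len(n_reads))

  world <- list(spec = spec, truth = structure(truth, names = nm),
                draft = draft, references = prim$seqs,
                secondary_references = if (is.null(sec)) NULL else sec$seqs,
                reads = rseqs, truth_errors = te, ref_pileup = ref_pileup,
                read_pileup = read_pileup, secondary_pileup = secondary_pileup)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(truth = file.path(dir, "truth.fasta"),
                  draft = file.path(dir, "draft.fasta"),
                  references = file.path(dir, "references.fasta"),
                  reads = file.path(dir, "reads.fasta"),
                  truth_errors = file.path(dir, "truth_errors.tsv"),
                  ref_pileup = file.path(dir, "references.pileup"),
                  read_pileup = file.path(dir, "reads.pileup"))
    write_fasta(world$truth, paths$truth)
    write_fasta(world$draft, paths$draft)
    write_fasta(world$references, paths$references)
    write_fasta(world$reads, paths$reads)
    write_error_table(te, paths$truth_errors)
    write_mpileup(ref_pileup, draft, paths$ref_pileup)
    write_mpileup(read_pileup, draft, paths$read_pileup)
    if (!is.null(secondary_pileup)) {
      paths$secondary_pileup <- file.path(dir, "secondary.pileup")
      paths$secondary_references <- file.path(dir, "secondary.fasta")
      write_mpileup(secondary_pileup, draft, paths$secondary_pileup)
      write_fasta(world$secondary_references, paths$secondary_references)
    }
    world$paths <- paths
  }
  world
}
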