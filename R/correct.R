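# Module three: apply the finalized error list to the draft assembly.

# Draft interval affected by one edit; deletion errors are zero-width
# insertion points anchored after `position`.
edit_interval <- function(errors) {
  s <- errors$position
  e <- ifelse(errors$error_type == "deletion", errors$position,
              errors$position + errors$length - 1L)
  # represent the deletion-error insertion point as (pos+0.5, pos+0.5)
  s <- ifelse(errors$error_type == "deletion", errors$position + 0.5, s)
  e <- ifelse(errors$error_type == "deletion", errors$position + 0.5, e)
  data.frame(start = s, end = e)
}

#' Apply an error list to a draft assembly
#'
#' Edits are validated against the draft (the recorded draft bases must still
#' be present), checked for overlap, and applied per contig in descending
#' coordinate order so earlier coordinates never shift: substitutions replace
#' \code{length} bases with \code{correction_seq}, insertion errors delete
#' \code{length} draft bases, deletion errors insert \code{correction_seq}
#' after the anchor position. Rows with status \code{"removed"} are skipped.
#' All positions refer to original draft coordinates.
#'
#' @param draft Named character vector of draft contigs.
#' @param errors Error data.frame.
#' @return Named character vector: the corrected assembly, contig order and
#'   names preserved.
#' @export
apply_errors <- function(draft, errors) {
  validate_errors(errors)
  errors <- errors[errors$status != "removed", , drop = FALSE]
  out <- draft
  for (contig in unique(errors$contig)) {
    if (!contig %in% names(draft))
      stop("error list names unknown contig ", contig, call. = FALSE)
    ed <- errors[errors$contig == contig, , drop = FALSE]
    seq <- draft[[contig]]
    L <- nchar(seq)

    iv <- edit_interval(ed)
    o <- order(iv$start, iv$end)
    if (any(iv$start[o][-1L] <= iv$end[o][-nrow(ed)]))
      stop("overlapping or duplicate edits on contig ", contig,
           " (corrupt error list)", call. = FALSE)

    expect <- ifelse(ed$error_type == "deletion", "",
                     substr(rep(seq, nrow(ed)), ed$position,
                            ed$position + ed$length - 1L))
    bad <- which(expect != ed$draft_seq)
    if (length(bad))
      stop(sprintf(
        "draft sequence mismatch at %s:%d (expected '%s', list says '%s'): stale error list",
        contig, ed$position[bad[1]], expect[bad[1]], ed$draft_seq[bad[1]]),
        call. = FALSE)
    if (any(ed$error_type != "deletion" & ed$position + ed$length - 1L > L))
      stop("edit overruns contig ", contig, call. = FALSE)

    ed <- ed[order(-ed$position, match(ed$error_type, ERROR_TYPES)), ,
             drop = FALSE]
    for (i in seq_len(nrow(ed))) {
      p <- ed$position[i]
      if (ed$error_type[i] == "substitution") {
        seq <- paste0(substr(seq, 1L, p - 1L), ed$correction_seq[i],
                      substr(seq, p + ed$length[i], nchar(seq)))
      } else if (ed$error_type[i] == "insertion") {
        seq <- paste0(substr(seq, 1L, p - 1L),
                      substr(seq, p + ed$length[i], nchar(seq)))
      } else {
        seq <- paste0(substr(seq, 1L, p), ed$correction_seq[i],
                      substr(seq, p + 1L, nchar(seq)))
      }
    }
    out[[contig]] <- seq
  }
  out
}

#' Reproduce an assembly correction from its error table
#'
#' Reads a previously written error TSV and the original draft, applies the
#' corrections, and writes the corrected FASTA — byte-identical to the file
#' the full pipeline run that generated the table would write. On any
#' failure, no partial output file is left behind.
#'
#' @param draft_path Draft FASTA path.
#' @param table_path Error TSV path (from \code{\link{write_error_table}}).
#' @param out_path Output FASTA path.
#' @return \code{out_path}, invisibly.
#' @export
reapply_from_table <- function(draft_path, table_path, out_path) {
  draft <- read_fasta(draft_path)
  errors <- read_error_table(table_path)
  corrected <- apply_errors(draft, errors)
  tmp <- tempfile(tmpdir = dirname(out_path), fileext = ".fasta.tmp")
  on.exit(unlink(tmp), add = TRUE)
  write_fasta(corrected, tmp)
  file.rename(tmp, out_path)
  invisible(out_path)
}

# Inverse edit list: swaps insertion/deletion roles and draft/correction
# sequences so that applying it to the corrected assembly restores the draft.
# Positions are remapped to corrected-assembly coordinates.
invert_errors <- function(errors) {
  errors <- sort_errors(errors[errors$status != "removed", , drop = FALSE])
  out <- errors
  for (contig in unique(errors$contig)) {
    idx <- which(errors$contig == contig)
    shift <- 0L
    for (i in idx) {
      type <- errors$error_type[i]
      out$position[i] <- errors$position[i] + shift
      if (type == "insertion") {
        out$error_type[i] <- "deletion"
        out$position[i] <- errors$position[i] + shift - 1L
        out$correction_seq[i] <- errors$draft_seq[i]
        out$draft_seq[i] <- ""
        shift <- shift - errors$length[i]
      } else if (type == "deletion") {
        out$error_type[i] <- "insertion"
        out$position[i] <- errors$position[i] + shift + 1L
        out$draft_seq[i] <- errors$correction_seq[i]
        out$correction_seq[i] <- ""
        shift <- shift + errors$length[i]
      } else {
        out$draft_seq[i] <- errors$correction_seq[i]
        out$correction_seq[i] <- errors$draft_seq[i]
      }
    }
  }
  out
}
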