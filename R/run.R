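#' Full polishing workflow: detect, adjust, correct
#'
#' Runs the three-module workflow end to end from file inputs and writes
#' \code{corrected.fasta}, \code{errors.tsv}, a run manifest (effective
#' configuration plus input checksums) and a plain-text log under
#' \code{outdir}. No corrected FASTA is left behind if any stage fails.
#'
#' @param draft_path Draft assembly FASTA.
#' @param ref_pileup_path All-positions mpileup of the reference set against
#'   the draft.
#' @param read_pileup_path Optional mpileup of raw reads against the draft;
#'   when absent, substitution candidates cannot be confirmed and are
#'   excluded from the output.
#' @param secondary_pileup_path Optional mpileup of a secondary reference
#'   set, used only where the primary set fails the coverage gate.
#' @param config A \code{\link{polish_config}}.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with \code{errors}, \code{corrected} and output
#'   \code{paths}.
#' @export
polish_assembly <- function(draft_path, ref_pileup_path,
                            read_pileup_path = NULL,
                            secondary_pileup_path = NULL,
                            config = polish_config(), outdir = ".") {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)

  draft <- read_fasta(draft_path)
  logf("draft: %d contig(s), %d nt total", length(draft),
       sum(nchar(draft)))
  ref_pileup <- parse_mpileup(ref_pileup_path, draft)
  read_pileup <- if (!is.null(read_pileup_path))
    parse_mpileup(read_pileup_path, draft) else NULL
  secondary <- if (!is.null(secondary_pileup_path))
    parse_mpileup(secondary_pileup_path, draft) else NULL

  cand <- detect_errors(ref_pileup, draft, config, secondary)
  logf("detected %d candidate error(s): %s", nrow(cand),
       count_by(cand$error_type))
  final <- adjust_errors(cand, draft, read_pileup, config)
  logf("after adjustment %d error(s): %s | status: %s", nrow(final),
       count_by(final$error_type), count_by(final$status))
  corrected <- apply_errors(draft, final)

  tsv_path <- file.path(outdir, "errors.tsv")
  fasta_path <- file.path(outdir, "corrected.fasta")
  write_error_table(final, tsv_path)
  tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  write_fasta(corrected, tmp)
  file.rename(tmp, fasta_path)

  manifest <- list(
    config = unclass(config),
    inputs = list(
      draft = list(path = draft_path, md5 = tools::md5sum(draft_path)[[1]]),
      ref_pileup = list(path = ref_pileup_path,
                        md5 = tools::md5sum(ref_pileup_path)[[1]]),
      read_pileup = if (is.null(read_pileup_path)) NULL else
        list(path = read_pileup_path,
             md5 = tools::md5sum(read_pileup_path)[[1]]),
      secondary_pileup = if (is.null(secondary_pileup_path)) NULL else
        list(path = secondary_pileup_path,
             md5 = tools::md5sum(secondary_pileup_path)[[1]])),
    n_errors = nrow(final),
    by_type = as.list(table(final$error_type)),
    by_status = as.list(table(final$status)))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  logf("wrote %s, %s, %s", fasta_path, tsv_path, manifest_path)
  invisible(list(errors = final, corrected = corrected,
                 paths = list(corrected = fasta_path, errors = tsv_path,
                              manifest = manifest_path, log = log_path)))
}

count_by <- function(x) {
  if (length(x) == 0L) return("none")
  tb <- table(x)
  paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = " ")
}
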