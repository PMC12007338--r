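ERROR_TYPES <- c("substitution", "insertion", "deletion")
ERROR_STATUSES <- c("detected", "confirmed", "adjusted", "split",
                    "retained_unsupported", "removed")
ERROR_COLUMNS <- c("contig", "position", "error_type", "length", "draft_seq",
                   "correction_seq", "reference_adp", "regional_adp", "score",
                   "read_adp", "status", "original_position")

# One row per candidate/finalized error. Error types are defined from the
# draft's perspective: an "insertion" error means the draft carries spurious
# bases (correction removes them, correction_seq == ""); a "deletion" error
# means the draft is missing bases (correction_seq is inserted after
# `position`, draft_seq == ""); a substitution replaces draft_seq with
# correction_seq at `position`. Positions are 1-based draft coordinates.
new_error_df <- function(contig = character(), position = integer(),
                         error_type = character(), length = integer(),
                         draft_seq = character(), correction_seq = character(),
                         reference_adp = numeric(), regional_adp = numeric(),
                         score = numeric(), read_adp = numeric(),
                         status = character(), original_position = integer(),
                         pass_found = integer()) {
  if (base::length(pass_found) == 0L && base::length(position) > 0L)
    pass_found <- rep(NA_integer_, base::length(position))
  if (base::length(read_adp) == 0L && base::length(position) > 0L)
    read_adp <- rep(NA_real_, base::length(position))
  data.frame(contig = contig, position = as.integer(position),
             error_type = error_type, length = as.integer(length),
             draft_seq = draft_seq, correction_seq = correction_seq,
             reference_adp = reference_adp, regional_adp = regional_adp,
             score = score, read_adp = read_adp, status = status,
             original_position = as.integer(original_position),
             pass_found = as.integer(pass_found), stringsAsFactors = FALSE)
}

validate_errors <- function(errors) {
  miss <- setdiff(ERROR_COLUMNS, names(errors))
  if (length(miss))
    stop("error table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(errors) == 0L) return(invisible(errors))
  bad <- !(errors$error_type %in% ERROR_TYPES)
  if (any(bad))
    stop("unknown error_type token: ", errors$error_type[which(bad)[1]],
         call. = FALSE)
  bad <- !(errors$status %in% ERROR_STATUSES)
  if (any(bad))
    stop("unknown status token: ", errors$status[which(bad)[1]], call. = FALSE)
  if (any(is.na(errors$position)) || any(errors$position < 1L))
    stop("non-positive or non-integer position in error table", call. = FALSE)
  if (any(errors$draft_seq == errors$correction_seq))
    stop("error row with draft_seq identical to correction_seq", call. = FALSE)
  invisible(errors)
}

sort_errors <- function(errors) {
  o <- order(errors$contig, errors$position,
             match(errors$error_type, ERROR_TYPES))
  out <- errors[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an error list to TSV
#'
#' Deterministically sorted by (contig, position, type); the file is a
#' complete record of the run and can be fed back to
#' \code{\link{reapply_from_table}} to reproduce the assembly correction.
#' Empty sequence fields are encoded as \code{"."}.
#'
#' @param errors Error data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_error_table <- function(errors, path) {
  validate_errors(errors)
  out <- sort_errors(errors)[ERROR_COLUMNS]
  out$draft_seq[out$draft_seq == ""] <- "."
  out$correction_seq[out$correction_seq == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an error list from TSV
#'
#' Rows with status \code{"removed"} are parsed but flagged non-applicable
#' (the corrector skips them).
#'
#' @param path Path written by \code{\link{write_error_table}}.
#' @return Error data.frame.
#' @export
read_error_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(contig = "character",
                                         draft_seq = "character",
                                         correction_seq = "character",
                                         error_type = "character",
                                         status = "character"),
                          na.strings = "NA")
  miss <- setdiff(ERROR_COLUMNS, names(df))
  if (length(miss))
    stop("error table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (!is.numeric(df$position))
      stop("non-integer position column in ", path, call. = FALSE)
    df$position <- as.integer(df$position)
    df$length <- as.integer(df$length)
    df$original_position <- as.integer(df$original_position)
    df$draft_seq[df$draft_seq == "."] <- ""
    df$correction_seq[df$correction_seq == "."] <- ""
  }
  df$pass_found <- rep(NA_integer_, nrow(df))
  validate_errors(df)
  sort_errors(df)
}
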