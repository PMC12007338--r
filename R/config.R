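#' Configuration for reference-comparative polishing
#'
#' Collects every threshold and schedule knob of the detection, adjustment and
#' correction workflow, with the defaults the method was calibrated with.
#'
#' @param error_threshold Fraction of covering references that must report the
#'   same alignment difference for a candidate error to be emitted. The
#'   default 0.99 means that with 15 or fewer references, 100% of covering
#'   genomes must exhibit the difference.
#' @param regional_trigger Positional alignment-difference probability (ADP)
#'   at or above which a column triggers regional evaluation (default 0.25).
#' @param min_ref_coverage Minimum number of reference genomes that must cover
#'   a column before it can be assessed (default 5).
#' @param max_indel_len Longest indel, in nucleotides, treated as a candidate
#'   assembly error; longer alignment indels are taken as genuine variants and
#'   ignored (default 2).
#' @param elective_passes Number of elective scan passes run after the two
#'   mandatory passes (default 4).
#' @param third_pass_window Window width, in nucleotides, of the first
#'   elective pass (default 11: five nucleotides flanking each side).
#' @param window_growth Nucleotides added to each side of the window per
#'   elective pass beyond the first (default 5).
#' @param strategy_stride Elective-pass stride at which the two extra search
#'   strategies (window shifting, alternative-length merging) are enabled;
#'   the default 2 enables them on every second elective pass.
#' @param adjust_threshold_sub Minimum read ADP for a substitution candidate
#'   to be confirmed rather than removed (default 0.10).
#' @param adjust_threshold_indel Minimum read ADP for an indel candidate site
#'   to count as read-supported (default 0.25).
#' @param adjust_window Width of the read-evidence search window centred on a
#'   candidate indel (default 21, must be odd).
#'
#' @return A list of class \code{polish_config}.
#' @export
polish_config <- function(error_threshold = 0.99,
                          regional_trigger = 0.25,
                          min_ref_coverage = 5L,
                          max_indel_len = 2L,
                          elective_passes = 4L,
                          third_pass_window = 11L,
                          window_growth = 5L,
                          strategy_stride = 2L,
                          adjust_threshold_sub = 0.10,
                          adjust_threshold_indel = 0.25,
                          adjust_window = 21L) {
  cfg <- list(error_threshold = error_threshold,
              regional_trigger = regional_trigger,
              min_ref_coverage = as.integer(min_ref_coverage),
              max_indel_len = as.integer(max_indel_len),
              elective_passes = as.integer(elective_passes),
              third_pass_window = as.integer(third_pass_window),
              window_growth = as.integer(window_growth),
              strategy_stride = as.integer(strategy_stride),
              adjust_threshold_sub = adjust_threshold_sub,
              adjust_threshold_indel = adjust_threshold_indel,
              adjust_window = as.integer(adjust_window))
  validate_config(cfg)
  class(cfg) <- "polish_config"
  cfg
}

validate_config <- function(cfg) {
  frac <- c("error_threshold", "regional_trigger",
            "adjust_threshold_sub", "adjust_threshold_indel")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in (0, 1]; got %s",
                   f, format(v)), call. = FALSE)
  }
  for (f in c("third_pass_window", "adjust_window")) {
    v <- cfg[[f]]
    if (v < 1L || v %% 2L == 0L)
      stop(sprintf("config field '%s' must be an odd window width >= 1", f),
           call. = FALSE)
  }
  if (cfg$max_indel_len < 1L) stop("max_indel_len must be >= 1", call. = FALSE)
  if (cfg$min_ref_coverage < 1L) stop("min_ref_coverage must be >= 1", call. = FALSE)
  if (cfg$elective_passes < 0L) stop("elective_passes must be >= 0", call. = FALSE)
  if (cfg$window_growth < 0L) stop("window_growth must be >= 0", call. = FALSE)
  if (cfg$strategy_stride < 1L) stop("strategy_stride must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.polish_config <- function(x, ...) {
  cat("<polish_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

n_passes <- function(config) 2L + config$elective_passes
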