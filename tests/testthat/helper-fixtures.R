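# Fixture builders and independent oracles. Everything is generated in code;
# no stored data files.

# Build a pileup directly from a per-source description:
#   sources = list(list(start=, end=, events=data.frame(pos,type,len,seq)), ...)
make_pileup <- function(draft, sources) {
  contig <- names(draft)[1]
  cov <- do.call(rbind, lapply(seq_along(sources), function(i)
    data.frame(source = i, start = sources[[i]]$start,
               end = sources[[i]]$end)))
  evs <- do.call(rbind, lapply(seq_along(sources), function(i) {
    ev <- sources[[i]]$events
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    data.frame(source = i, ev, stringsAsFactors = FALSE)
  }))
  if (is.null(evs))
    evs <- data.frame(source = integer(), pos = integer(), type = character(),
                      len = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  refpolish:::pileup_from_tables(draft, stats::setNames(list(cov), contig),
                                 stats::setNames(list(evs), contig),
                                 length(sources))
}

ev <- function(pos, type, seq) {
  data.frame(pos = pos, type = type, len = nchar(seq), seq = seq,
             stringsAsFactors = FALSE)
}

no_ev <- function() {
  data.frame(pos = integer(), type = character(), len = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

# n sources covering [1, L] where `with_events[[i]]` gives source i's events.
full_cov_sources <- function(n, L, with_events = list()) {
  lapply(seq_len(n), function(i) {
    e <- if (i <= length(with_events) && !is.null(with_events[[i]]))
      with_events[[i]] else no_ev()
    list(start = 1L, end = L, events = e)
  })
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")

# Random pileup for property tests: every source covers a random range and
# carries random events (one per position per source, deletions shadow the
# following positions).
random_pileup <- function(L = 200L, n_sources = 10L) {
  draft <- c(ctg = random_seq(L))
  sources <- lapply(seq_len(n_sources), function(i) {
    start <- sample.int(max(1L, L %/% 4L), 1L)
    end <- L - sample.int(max(1L, L %/% 4L), 1L) + 1L
    if (end <= start + 10L) { start <- 1L; end <- L }
    pos <- sort(sample(start:(end - 3L), sample(0:8, 1L)))
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) > 3L)]
    if (length(pos) == 0L) return(list(start = start, end = end, events = no_ev()))
    type <- sample(c("mismatch", "ins", "del"), length(pos), TRUE)
    len <- ifelse(type == "mismatch", 1L, sample(1:3, length(pos), TRUE))
    seq <- vapply(seq_along(pos), function(j) {
      if (type[j] == "mismatch")
        sample(setdiff(c("A", "C", "G", "T"),
                       substr(draft[[1]], pos[j], pos[j])), 1L)
      else if (type[j] == "ins")
        random_seq(len[j])
      else substr(draft[[1]], pos[j] + 1L, pos[j] + len[j])
    }, "")
    list(start = start, end = end,
         events = data.frame(pos = pos, type = type, len = len, seq = seq,
                             stringsAsFactors = FALSE))
  })
  list(draft = draft, pileup = make_pileup(draft, sources),
       sources = sources)
}

# Independent oracle: recount a positional ADP straight from the per-source
# description, never touching the package's event tables.
oracle_positional <- function(sources, pos, error_type, max_len = 2L) {
  covering <- 0L
  hits <- 0L
  for (s in sources) {
    covers <- s$start <= pos && s$end >= pos
    if (!covers) next
    covering <- covering + 1L
    e <- s$events
    for (j in seq_len(nrow(e))) {
      if (e$pos[j] != pos) next
      hit <- switch(error_type,
                    substitution = e$type[j] == "mismatch" && e$seq[j] != "N",
                    insertion = e$type[j] == "del" && e$len[j] <= max_len,
                    deletion = e$type[j] == "ins" && e$len[j] <= max_len)
      if (hit) hits <- hits + 1L
    }
  }
  list(adp = if (covering > 0L) hits / covering else NA_real_,
       numerator = hits, depth = covering)
}

# Independent oracle for the regional ADP: exhaustive loop over sources and
# window columns, counting each source at most once.
oracle_regional <- function(sources, window, error_type, trigger_pos,
                            max_len = 2L) {
  den <- 0L
  num <- 0L
  for (s in sources) {
    if (!(s$start <= trigger_pos && s$end >= trigger_pos)) next
    den <- den + 1L
    e <- s$events
    found <- FALSE
    for (j in seq_len(nrow(e))) {
      if (e$pos[j] < window[1] || e$pos[j] > window[2]) next
      hit <- switch(error_type,
                    substitution = e$type[j] == "mismatch" && e$seq[j] != "N",
                    insertion = e$type[j] == "del" && e$len[j] <= max_len,
                    deletion = e$type[j] == "ins" && e$len[j] <= max_len)
      if (hit) found <- TRUE
    }
    if (found) num <- num + 1L
  }
  list(adp = if (den > 0L) num / den else NA_real_,
       numerator = num, denominator = den)
}

# Small synthetic world used by several test files.
small_world <- function(seed = 42L, L = 20000L, ...) {
  spec <- simulation_spec(
    genome_length = L, n_references = 10L,
    errors = within(error_mix(), n <- c(3L, 4L, 2L, 2L, 3L, 2L)),
    read_depth = 30, read_length = 3000L,
    read_sub_rate = 0, read_indel_rate = 0, seed = seed, ...)
  simulate_world(spec)
}

error_key <- function(df) paste(df$contig, df$position, df$error_type)
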