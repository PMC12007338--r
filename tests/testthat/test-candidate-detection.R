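# Module one: positional/regional ADP, window schedule, scoring, detection.

test_that("positional ADP matches hand computations per error type", {
  L <- 50L
  draft <- c(ctg = paste0(strrep("AC", 20L), "GGGGGTTTTT"))
  # 10 refs all mismatch A->G at pos 11; 8 of 10 carry a 1-nt deletion at 20;
  # all carry a 3-nt insertion at 30 (too long, must be ignored)
  evs <- lapply(1:10, function(i) {
    e <- ev(11L, "mismatch", "G")
    if (i <= 8) e <- rbind(e, ev(20L, "del", substr(draft[[1]], 21L, 21L)))
    rbind(e, ev(30L, "ins", "AGT"))
  })
  pu <- make_pileup(draft, full_cov_sources(10L, L, evs))

  sub <- positional_adp(pu, "ctg", 11L, "substitution")
  expect_equal(sub$adp, 1.0)
  expect_equal(unname(sub$detail[["G"]]), 10L)

  insE <- positional_adp(pu, "ctg", 20L, "insertion")
  expect_equal(insE$adp, 0.8)

  delE <- positional_adp(pu, "ctg", 30L, "deletion")
  expect_equal(delE$adp, 0.0)  # 3-nt events are ignored entirely

  # N mismatches cover but never count
  evs_n <- c(lapply(1:5, function(i) ev(11L, "mismatch", "N")),
             lapply(1:5, function(i) ev(11L, "mismatch", "T")))
  pu_n <- make_pileup(draft, full_cov_sources(10L, L, evs_n))
  sub_n <- positional_adp(pu_n, "ctg", 11L, "substitution")
  expect_equal(sub_n$adp, 0.5)
  expect_identical(sub_n$depth, 10L)
})

test_that("coverage gate is inclusive at the minimum", {
  draft <- c(ctg = random_seq(30L))
  mk <- function(n) make_pileup(draft, full_cov_sources(n, 30L))
  expect_true(coverage_gate(mk(5L), "ctg", 10L, 5L))
  expect_false(coverage_gate(mk(4L), "ctg", 10L, 5L))
  # all-positions pileup, truly uncovered column
  pu <- make_pileup(draft, list(list(start = 1L, end = 10L, events = no_ev())))
  expect_false(coverage_gate(pu, "ctg", 20L, 5L))
})

test_that("window schedule follows the pass structure", {
  seq <- paste0(strrep("GC", 47L), "G", "AAAAA", strrep("TC", 50L))  # run at 96..100
  w1 <- window_schedule(1L, seq, 100L)
  expect_identical(c(w1$start, w1$end), c(100L, 100L))
  w2 <- window_schedule(2L, seq, 98L)
  expect_identical(c(w2$start, w2$end), c(96L, 100L))
  w3 <- window_schedule(3L, seq, 100L)
  expect_identical(c(w3$start, w3$end), c(95L, 105L))
  w4 <- window_schedule(4L, seq, 100L)
  expect_identical(c(w4$start, w4$end), c(90L, 110L))
  expect_false(w3$shift_enabled)
  expect_true(w4$shift_enabled)   # second elective pass
  expect_false(window_schedule(5L, seq, 100L)$shift_enabled)
  expect_true(window_schedule(6L, seq, 100L)$merge_enabled)
  # truncation at contig ends
  wt <- window_schedule(4L, seq, 5L)
  expect_identical(c(wt$start, wt$end), c(1L, 15L))
  expect_error(window_schedule(7L, seq, 5L), "out of range")
})

test_that("regional ADP deduplicates per source", {
  L <- 60L
  draft <- c(ctg = random_seq(L))
  # one ref shows 3 deletions in the window, the other 9 none
  evs <- list(rbind(ev(20L, "del", substr(draft[[1]], 21L, 21L)),
                    ev(25L, "del", substr(draft[[1]], 26L, 26L)),
                    ev(30L, "del", substr(draft[[1]], 31L, 31L))))
  pu <- make_pileup(draft, full_cov_sources(10L, L, evs))
  r <- regional_adp(pu, "ctg", c(15L, 35L), "insertion", 25L)
  expect_equal(r$adp, 0.1)
  expect_identical(r$numerator, 1L)

  # every ref with >= 1 same-type difference somewhere in the window -> 1.0
  evs_all <- lapply(1:10, function(i)
    ev(14L + i, "del", substr(draft[[1]], 15L + i, 15L + i)))
  pu2 <- make_pileup(draft, full_cov_sources(10L, L, evs_all))
  expect_equal(regional_adp(pu2, "ctg", c(15L, 35L), "insertion", 25L)$adp, 1.0)
})

test_that("positional and regional ADP agree with brute-force recounts", {
  set.seed(99)
  n_checked <- 0L
  for (i in 1:25) {
    rp <- random_pileup(L = 200L, n_sources = sample(7:15, 1L))
    for (j in 1:14) {
      pos <- sample.int(200L, 1L)
      type <- sample(refpolish:::ERROR_TYPES, 1L)
      got <- positional_adp(rp$pileup, "ctg", pos, type)
      want <- oracle_positional(rp$sources, pos, type)
      expect_identical(got$numerator, want$numerator)
      expect_identical(got$depth, want$depth)
      expect_equal(got$adp, want$adp)

      w <- sort(sample.int(200L, 2L))
      trig <- sample(w[1]:w[2], 1L)
      gotr <- regional_adp(rp$pileup, "ctg", w, type, trig)
      wantr <- oracle_regional(rp$sources, w, type, trig)
      expect_identical(gotr$numerator, wantr$numerator)
      expect_identical(gotr$denominator, wantr$denominator)
      expect_equal(gotr$adp, wantr$adp)
      n_checked <- n_checked + 2L
    }
  }
  expect_gte(n_checked, 700L)
})

test_that("site scores weight homopolymer length and penalize run splits", {
  # draft has a TTTTT run at exactly 21..25; 6 of 10 refs mismatch T->C at 23
  draft <- c(ctg = paste0(strrep("GA", 10L), "TTTTT", strrep("CG", 10L)))
  evs <- lapply(1:6, function(i) ev(23L, "mismatch", "C"))
  pu <- make_pileup(draft, full_cov_sources(10L, 45L, evs))
  # mismatch frequency 0.6 x run length 5, halved because replacing the
  # middle T with C breaks the run
  site <- score_region(pu, draft, "ctg", c(18L, 28L), "substitution")
  expect_equal(site$score, 0.6 * 5 * 0.5)
  expect_identical(site$position, 23L)

  # at the run edge there is no split penalty
  evs2 <- lapply(1:6, function(i) ev(21L, "mismatch", "C"))
  pu2 <- make_pileup(draft, full_cov_sources(10L, 45L, evs2))
  site2 <- score_region(pu2, draft, "ctg", c(18L, 28L), "substitution")
  expect_equal(site2$score, 0.6 * 5)

  # tie on score -> leftmost site wins (alternating bases: runs of length 1)
  evs3 <- list(ev(5L, "mismatch", "A"), ev(5L, "mismatch", "A"),
               ev(8L, "mismatch", "A"), ev(8L, "mismatch", "A"))
  draft3 <- c(ctg = paste0("GCGCGCGCGC", strrep("GC", 10L)))
  pu3 <- make_pileup(draft3, full_cov_sources(4L, 30L, evs3))
  site3 <- score_region(pu3, draft3, "ctg", c(1L, 10L), "substitution")
  expect_identical(site3$position, 5L)
})

test_that("same-homopolymer same-type locations merge before scoring", {
  # AAAAA run at 11..15; refs report a 1-nt A insertion at different anchors
  # within the run: supports must pool per source, deduplicated
  draft <- c(ctg = paste0(strrep("CT", 5L), "AAAAA", strrep("GC", 10L)))
  evs <- c(lapply(1:4, function(i) ev(10L, "ins", "A")),
           lapply(1:4, function(i) ev(13L, "ins", "A")))
  # sources 5..8 anchor at 13, sources 1..4 at 10; one source double-reports
  evs[[1]] <- rbind(ev(10L, "ins", "A"), ev(14L, "ins", "A"))
  pu <- make_pileup(draft, full_cov_sources(8L, 35L, evs))
  site <- score_region(pu, draft, "ctg", c(8L, 18L), "deletion")
  # all 8 sources support inserting an A into the run: freq 1.0 x length 5
  expect_equal(site$support_frac, 1.0)
  expect_equal(site$score, 5)
  expect_identical(site$correction_seq, "A")
})

test_that("zero-divergence world is recovered exactly, gated by coverage", {
  w <- small_world(seed = 5L)
  cand <- detect_errors(w$ref_pileup, w$draft)
  expect_identical(error_key(cand), error_key(w$truth_errors))
  expect_true(all(cand$reference_adp == 1))
  expect_identical(cand$correction_seq, w$truth_errors$correction_seq)
  expect_identical(cand$length, w$truth_errors$length)

  # raising the coverage gate above the reference count empties the result
  cfg <- polish_config(min_ref_coverage = 11L)
  expect_identical(nrow(detect_errors(w$ref_pileup, w$draft, cfg)), 0L)
})

test_that("full-consensus emission holds at threshold 0.99", {
  w <- small_world(seed = 8L)
  cand <- detect_errors(w$ref_pileup, w$draft)
  for (i in seq_len(nrow(cand))) {
    # indel evidence anchors on the draft base preceding the event
    anchor <- if (cand$error_type[i] == "insertion") cand$position[i] - 1L
              else cand$position[i]
    r <- regional_adp(w$ref_pileup, cand$contig[i], c(anchor, anchor),
                      cand$error_type[i], anchor)
    expect_identical(r$numerator, r$denominator)
    expect_gt(r$denominator, 0L)
  }
})

test_that("raising the error threshold never increases the candidate count", {
  spec <- simulation_spec(genome_length = 20000L, n_references = 8L,
                          ref_sub_rate = 0.03, ref_indel_rate = 0.004,
                          errors = within(error_mix(),
                                          n <- c(3L, 4L, 2L, 2L, 3L, 2L)),
                          read_depth = 5, read_length = 2000L, seed = 31L)
  w <- simulate_world(spec)
  counts <- vapply(c(0.5, 0.75, 0.9, 0.99), function(thr)
    nrow(detect_errors(w$ref_pileup, w$draft,
                       polish_config(error_threshold = thr))), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("detection is deterministic", {
  w <- small_world(seed = 12L)
  a <- detect_errors(w$ref_pileup, w$draft)
  b <- detect_errors(w$ref_pileup, w$draft)
  expect_identical(a, b)
})

test_that("a secondary reference set rescues low-coverage regions", {
  spec <- simulation_spec(genome_length = 20000L, n_references = 10L,
                          errors = within(error_mix(),
                                          n <- c(3L, 4L, 2L, 2L, 3L, 2L)),
                          uncovered_region = c(8000L, 12000L),
                          n_secondary = 6L,
                          read_depth = 5, read_length = 2000L, seed = 77L)
  w <- simulate_world(spec)
  te <- w$truth_errors
  hidden <- te$position >= 8000L & te$position <= 12000L
  expect_gt(sum(hidden), 0L)  # the fixed seed places errors in the region

  alone <- detect_errors(w$ref_pileup, w$draft)
  expect_false(any(error_key(te)[hidden] %in% error_key(alone)))

  both <- detect_errors(w$ref_pileup, w$draft,
                        secondary_pileup = w$secondary_pileup)
  expect_true(all(error_key(te)[hidden] %in% error_key(both)))
  expect_identical(error_key(both), error_key(te))
})

test_that("emitted candidates respect indel-length and coverage invariants", {
  spec <- simulation_spec(genome_length = 30000L, n_references = 9L,
                          ref_sub_rate = 0.04, ref_indel_rate = 0.005,
                          read_depth = 5, read_length = 2000L, seed = 55L)
  w <- simulate_world(spec)
  cfg <- polish_config()
  cand <- detect_errors(w$ref_pileup, w$draft, cfg)
  indels <- cand[cand$error_type != "substitution", ]
  expect_true(all(indels$length <= cfg$max_indel_len))
  depth <- w$ref_pileup$contigs$contig_1$depth
  expect_true(all(depth[cand$position] >= cfg$min_ref_coverage))
})
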