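# Module two: read ADP profiles, indel adjustment, substitution confirmation.

# 60-nt draft with an exactly-bounded AAAAA run at 21..25.
adj_draft <- function() c(ctg = paste0(strrep("GC", 10L), "AAAAA",
                                       strrep("TG", 10L), strrep("CT", 7L),
                                       "G"))

test_that("profile groups run-equivalent sites and isolates run breaks", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  # 30% of reads report a 1-nt A insertion somewhere in the AAAAA run, at
  # different anchors; 20% report a G insertion inside the run (a run break)
  evs <- c(lapply(1:3, function(i) ev(20L + i, "ins", "A")),
           lapply(1:2, function(i) ev(23L, "ins", "G")))
  pu <- make_pileup(draft, full_cov_sources(10L, L, evs))
  prof <- read_adp_profile(pu, draft, "ctg", c(15L, 35L), "deletion", 1L)
  a_row <- prof[prof$top_seq == "A", ]
  g_row <- prof[prof$top_seq == "G", ]
  expect_identical(nrow(a_row), 1L)   # one representative site for the run
  expect_equal(a_row$adp, 0.3)
  expect_identical(nrow(g_row), 1L)   # the break stays separate
  expect_equal(g_row$adp, 0.2)
  expect_false(a_row$key == g_row$key)
})

test_that("profile support equals a brute-force per-read recount", {
  set.seed(404)
  for (i in 1:8) {
    rp <- random_pileup(L = 120L, n_sources = 12L)
    runs <- homopolymer_runs(rp$draft[[1]])
    prof <- read_adp_profile(rp$pileup, rp$draft, "ctg", c(20L, 100L),
                             "insertion", 1L)
    for (j in seq_len(nrow(prof))) {
      rid <- runs$run_id[prof$site[j] + 1L]
      anchors <- which(runs$run_id == rid) - 1L   # anchors deleting this run
      support <- vapply(rp$sources, function(s) {
        e <- s$events
        any(e$type == "del" & e$len == 1L & e$pos %in% anchors &
              e$pos >= 20L & e$pos <= 100L & e$pos < 120L)
      }, logical(1))
      covering <- vapply(rp$sources, function(s)
        s$start <= prof$site[j] && s$end >= prof$site[j], logical(1))
      expect_identical(prof$n_support[j], sum(support))
      expect_equal(prof$adp[j], sum(support) / sum(covering))
    }
  }
})

make_candidate <- function(position, error_type, length = 1L, draft_seq = "",
                           correction_seq = "A", contig = "ctg") {
  refpolish:::new_error_df(
    contig = contig, position = position, error_type = error_type,
    length = length, draft_seq = draft_seq, correction_seq = correction_seq,
    reference_adp = 1, regional_adp = 1, score = 1, read_adp = NA_real_,
    status = "detected", original_position = position, pass_found = 1L)
}

test_that("indel support at exactly the threshold confirms in place", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  evs <- lapply(1:4, function(i) ev(21L, "ins", "A"))  # 4 of 16 reads = 0.25
  pu <- make_pileup(draft, full_cov_sources(16L, L, evs))
  cand <- make_candidate(21L, "deletion", correction_seq = "A")
  out <- adjust_indel(cand, pu, draft)
  expect_identical(out$status, "confirmed")
  expect_identical(out$position, 21L)
  expect_equal(out$read_adp, 0.25)
})

test_that("unsupported initial sites relocate to the best read site", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  # reference-detected deletion at 47 (draft C/T alternation: no run), but
  # reads put the missing C two nucleotides left, at anchor 45
  evs <- lapply(1:9, function(i) ev(45L, "ins", "C"))
  pu <- make_pileup(draft, full_cov_sources(15L, L, evs))
  cand <- make_candidate(47L, "deletion", correction_seq = "C")
  out <- adjust_indel(cand, pu, draft)
  expect_identical(out$status, "adjusted")
  expect_identical(out$position, 45L)
  expect_identical(out$original_position, 47L)
  expect_equal(out$read_adp, 0.6)
  expect_identical(out$correction_seq, "C")
})

test_that("no read support anywhere retains the indel unadjusted", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  pu <- make_pileup(draft, full_cov_sources(10L, L))
  cand <- make_candidate(30L, "insertion", draft_seq = "T",
                         correction_seq = "")
  out <- adjust_indel(cand, pu, draft)
  expect_identical(out$status, "retained_unsupported")
  expect_identical(out$position, 30L)
  expect_equal(out$read_adp, 0)
})

test_that("a 2-nt indel splits into two supported 1-nt indels", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  # no 2-nt read support; 1-nt insertions at anchors 43 (C) and 49 (T)
  evs <- c(lapply(1:8, function(i) ev(43L, "ins", "C")),
           lapply(9:18, function(i) ev(49L, "ins", "T")))
  evs_all <- vector("list", 20L)
  for (i in 1:8) evs_all[[i]] <- ev(43L, "ins", "C")
  for (i in 9:18) evs_all[[i]] <- ev(49L, "ins", "T")
  pu <- make_pileup(draft, full_cov_sources(20L, L, evs_all))
  cand <- make_candidate(46L, "deletion", length = 2L, correction_seq = "CT")
  out <- adjust_indel(cand, pu, draft)
  expect_identical(out$status, c("split", "split"))
  expect_identical(out$length, c(1L, 1L))          # 2 -> 1 + 1
  expect_identical(out$position, c(43L, 49L))
  expect_identical(out$correction_seq, c("C", "T"))
  expect_identical(out$original_position, c(46L, 46L))
  expect_identical(out$error_type, c("deletion", "deletion"))

  # only one supported 1-nt site: no split, retained instead
  pu1 <- make_pileup(draft, full_cov_sources(
    20L, L, lapply(1:8, function(i) ev(43L, "ins", "C"))))
  out1 <- adjust_indel(cand, pu1, draft)
  expect_identical(out1$status, "retained_unsupported")
  expect_identical(out1$position, 46L)
})

test_that("substitutions are confirmed by the best-supported alternative", {
  draft <- adj_draft()
  L <- nchar(draft[[1]])
  pos <- 41L  # draft base G
  expect_identical(substr(draft[[1]], pos, pos), "G")
  evs <- c(lapply(1:8, function(i) ev(pos, "mismatch", "A")),
           lapply(1:1, function(i) ev(pos, "mismatch", "T")))
  evs_all <- vector("list", 20L)
  for (i in 1:8) evs_all[[i]] <- ev(pos, "mismatch", "A")
  evs_all[[9]] <- ev(pos, "mismatch", "T")
  pu <- make_pileup(draft, full_cov_sources(20L, L, evs_all))
  cand <- make_candidate(pos, "substitution", draft_seq = "G",
                         correction_seq = "C")  # reference suggested C
  out <- confirm_substitution(cand, pu)
  expect_identical(out$status, "confirmed")
  expect_identical(out$correction_seq, "A")  # reads overrule the reference
  expect_equal(out$read_adp, 0.4)

  # all reads match the draft -> removed
  pu2 <- make_pileup(draft, full_cov_sources(20L, L))
  expect_identical(confirm_substitution(cand, pu2)$status, "removed")

  # support below the threshold -> removed
  evs3 <- vector("list", 20L)
  evs3[[1]] <- ev(pos, "mismatch", "A")
  pu3 <- make_pileup(draft, full_cov_sources(20L, L, evs3))
  out3 <- confirm_substitution(cand, pu3)
  expect_identical(out3$status, "removed")
  expect_equal(out3$read_adp, 0.05)
})

test_that("without reads, substitutions drop and indels pass through", {
  w <- small_world(seed = 19L)
  cand <- detect_errors(w$ref_pileup, w$draft)
  expect_gt(sum(cand$error_type == "substitution"), 0L)
  out <- adjust_errors(cand, w$draft, read_pileup = NULL)
  expect_identical(sum(out$error_type == "substitution"), 0L)
  indels <- cand[cand$error_type != "substitution", ]
  expect_identical(error_key(out), error_key(indels))
  expect_true(all(out$status == "retained_unsupported"))

  expect_identical(nrow(adjust_errors(cand[0, ], w$draft, NULL)), 0L)
})

test_that("adjustment conserves indels and never grows substitutions", {
  spec <- simulation_spec(genome_length = 30000L, n_references = 10L,
                          ref_sub_rate = 0.04, ref_indel_rate = 0.005,
                          read_depth = 30, read_length = 4000L, seed = 61L)
  w <- simulate_world(spec)
  cand <- detect_errors(w$ref_pileup, w$draft)
  out <- adjust_errors(cand, w$draft, w$read_pileup)
  n_ind_in <- sum(cand$error_type != "substitution")
  n_split <- sum(out$status == "split")
  n_ind_out <- sum(out$error_type != "substitution")
  expect_identical(n_ind_out, n_ind_in + n_split %/% 2L)
  expect_lte(sum(out$error_type == "substitution" & out$status != "removed"),
             sum(cand$error_type == "substitution"))
  expect_true(all(out$error_type %in% cand$error_type))
  moved <- out[!is.na(out$original_position) &
                 out$position != out$original_position, ]
  expect_true(all(abs(moved$position - moved$original_position) <= 10L))
  # with truth-derived reads, every surviving correction matches the truth
  corr <- apply_errors(w$draft, out)
  expect_identical(unname(corr), unname(w$truth))
})

test_that("mis-positioned homopolymer indels relocate to the true site", {
  errs <- data.frame(type = "deletion", length = 1L,
                     placement = "in_homopolymer", motif = NA_character_,
                     min_run = 3L, n = 25L, stringsAsFactors = FALSE)
  spec <- simulation_spec(genome_length = 40000L, n_references = 10L,
                          errors = errs, read_depth = 30,
                          read_length = 4000L, read_sub_rate = 0.01,
                          read_indel_rate = 0.002, seed = 13L)
  w <- simulate_world(spec)
  te <- w$truth_errors
  recovered <- logical(nrow(te))
  for (i in seq_len(nrow(te))) {
    offset <- (i %% 3L) + 1L                    # deliberate 1-3 nt shift
    cand <- te[i, , drop = FALSE]
    cand$position <- cand$position + offset
    cand$original_position <- cand$position
    out <- adjust_indel(cand, w$read_pileup, w$draft)
    if (nrow(out) != 1L || out$status == "retained_unsupported") next
    # semantic recovery: the adjusted edit must reproduce the true local state
    got <- apply_errors(w$draft, out)
    want <- apply_errors(w$draft, te[i, , drop = FALSE])
    recovered[i] <- identical(got, want)
  }
  expect_gte(mean(recovered), 0.95)
})
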