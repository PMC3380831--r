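mk_calls <- function(chrom, center, pl = 147L, occ = 100L, nm = occ,
                     mm = center, mv = 100) {
  n <- length(center)
  data.frame(chrom = chrom, center = as.integer(center),
             protected_length = rep_len(as.integer(pl), n),
             fuzziness = sqrt(rep_len(mv, n)),
             occupancy = rep_len(as.integer(occ), n),
             n_members = rep_len(as.integer(nm), n),
             member_mean = rep_len(as.numeric(mm), n),
             member_var = rep_len(as.numeric(mv), n),
             peak_density = 1, call_rank = seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("pairing follows the overlap and coverage rules", {
  # overlap 127 >= 30: paired
  p <- pair_calls(mk_calls("c", 1000L), mk_calls("c", 1020L))
  expect_identical(nrow(p), 1L)
  expect_identical(p$overlap_bp, 127L)
  expect_identical(p$consensus_dyad, 1010L)
  # overlap 17 < 30: unpaired
  p2 <- pair_calls(mk_calls("c", 1000L), mk_calls("c", 1130L))
  expect_identical(nrow(p2), 0L)
  expect_identical(attr(p2, "unpaired_t0"), 1L)
  expect_identical(attr(p2, "unpaired_t3"), 1L)
})

test_that("greedy pairing keeps the largest overlap only", {
  # one t3 call overlapping two t0 calls by different amounts
  t0 <- mk_calls("c", c(1000L, 1120L))
  t3 <- mk_calls("c", 1040L)
  p <- pair_calls(t0, t3)
  expect_identical(nrow(p), 1L)
  expect_identical(p$center_t0, 1000L)   # overlap 107 beats 67
  expect_identical(attr(p, "unpaired_t0"), 2L)
})

test_that("equal overlaps resolve to the leftmost 0 h center", {
  t0 <- mk_calls("c", c(1000L, 1080L))
  t3 <- mk_calls("c", 1040L)   # overlap 107 with both
  p <- pair_calls(t0, t3)
  expect_identical(p$center_t0, 1000L)
})

test_that("the coverage filter applies before matching", {
  # low-coverage t0 call would otherwise win the overlap
  t0 <- rbind(mk_calls("c", 1000L, occ = 3L), mk_calls("c", 1100L))
  t0$call_rank <- 1:2
  t3 <- mk_calls("c", 1010L)
  p <- pair_calls(t0, t3)
  expect_identical(p$idx_t0, 2L)  # paired with the distant covered call
  expect_identical(p$center_t0, 1100L)
})

test_that("welch_p matches t.test on summary statistics", {
  withr::local_seed(42)
  for (i in 1:100) {
    n0 <- sample(5:200, 1); n1 <- sample(5:200, 1)
    x <- rnorm(n0, 0, runif(1, 5, 20))
    y <- rnorm(n1, runif(1, -10, 10), runif(1, 5, 20))
    want <- t.test(x, y)$p.value
    got <- dyadcall:::welch_p(n0, mean(x), var(x), n1, mean(y), var(y))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("binomial occupancy tails match the exact oracle", {
  k0 <- c(0L, 10L, 50L, 100L, 3L)
  k3 <- c(0L, 10L, 20L, 300L, 0L)
  occ <- classify_occupancy(k0, k3, n_tests = 1L)
  n <- k0 + k3
  expect_equal(occ$occ_p_lower, oracle_binom_lower(k3, n), tolerance = 1e-12)
  expect_equal(occ$occ_p_upper, oracle_binom_upper(k3, n), tolerance = 1e-12)
  expect_identical(occ$occupancy_call[1L], "no_call")  # n = 0
  expect_error(classify_occupancy(-1L, 5L, 1L), "negative")
})

test_that("occupancy verdicts follow the thresholds", {
  n_tests <- 10L
  # strong loss, strong gain, balanced
  occ <- classify_occupancy(c(200L, 50L, 100L), c(50L, 200L, 101L), n_tests)
  expect_identical(occ$occupancy_call, c("reduced", "retained", "unchanged"))
  # borderline: raw lower tail outside (0.2, 0.8) but not significant
  occ2 <- classify_occupancy(120L, 100L, n_tests)
  expect_identical(occ2$occupancy_call, "no_call")
})

test_that("position verdicts follow the thresholds and report shifts", {
  base <- pair_calls(mk_calls("c", 1000L), mk_calls("c", 1030L))
  # inject member statistics implying a clear 30 bp shift
  base$member_mean_t0 <- 1000; base$member_mean_t3 <- 1030
  base$member_var_t0 <- 100; base$member_var_t3 <- 100
  base$n_members_t0 <- 200L; base$n_members_t3 <- 200L
  pos <- classify_position(base, n_tests = 100L)
  expect_identical(pos$position_call, "altered")
  expect_identical(pos$shift_bp, 30L)
  expect_identical(pos$shift_direction, "right")
  # identical member distributions: unchanged
  base$member_mean_t3 <- 1000.1
  pos2 <- classify_position(base, n_tests = 1L)
  expect_identical(pos2$position_call, "unchanged")
})

test_that("degenerate position tests fall back to no_call", {
  base <- pair_calls(mk_calls("c", 1000L), mk_calls("c", 1005L))
  base$n_members_t0 <- 1L
  pos <- classify_position(base, n_tests = 1L)
  expect_identical(pos$position_call, "no_call")
  expect_true(pos$position_degenerate)
  base$n_members_t0 <- 50L
  base$member_var_t0 <- 0; base$member_var_t3 <- 0
  pos2 <- classify_position(base, n_tests = 1L)
  expect_true(pos2$position_degenerate)
})

test_that("classify_pairs counts centers in the anchored window", {
  cs <- c(c = 5000L)
  t0 <- mk_calls("c", 1000L)
  t3 <- mk_calls("c", 1040L)
  pairs <- pair_calls(t0, t3)
  expect_identical(pairs$consensus_dyad, 1020L)
  # centers: 60 near 1000, 40 near 1040
  c0 <- center_list(list(c = rep(1000L, 60L)), cs)
  c3 <- center_list(list(c = rep(1040L, 40L)), cs)
  cons <- classify_pairs(pairs, c0, c3, anchor = "consensus")
  # both centers lie within 50 bp of the consensus dyad 1020
  expect_identical(cons$k0, 60L)
  expect_identical(cons$k3, 40L)
  resp <- classify_pairs(pairs, c0, c3, anchor = "respective")
  expect_identical(resp$k0, 60L)
  expect_identical(resp$k3, 40L)
  # fallback without center lists uses the call occupancies
  fall <- classify_pairs(pairs)
  expect_identical(fall$k0, pairs$occupancy_t0)
})

test_that("replicate consensus requires two agreeing informative labels", {
  mk_rep <- function(pos, occ) {
    data.frame(chrom = "c", center_t0 = 1000L, center_t3 = 1005L,
               position_call = pos, occupancy_call = occ,
               shift_bp = 5L, shift_direction = "right",
               stringsAsFactors = FALSE)
  }
  cons <- replicate_consensus(list(mk_rep("altered", "reduced"),
                                   mk_rep("altered", "no_call"),
                                   mk_rep("no_call", "reduced")))
  expect_identical(nrow(cons), 1L)
  expect_identical(cons$support, 3L)
  expect_identical(cons$consensus_position, "altered")
  expect_identical(cons$consensus_occupancy, "reduced")
  # single informative replicate is insufficient
  cons2 <- replicate_consensus(list(mk_rep("altered", "no_call"),
                                    mk_rep("no_call", "no_call")))
  expect_identical(cons2$consensus_position, "none")
  # equally supported competing labels cancel
  cons3 <- replicate_consensus(list(mk_rep("altered", "no_call"),
                                    mk_rep("altered", "no_call"),
                                    mk_rep("unchanged", "no_call"),
                                    mk_rep("unchanged", "no_call")))
  expect_identical(cons3$consensus_position, "none")
})

test_that("opposite occupancy classifications veto the consensus", {
  mk_rep <- function(occ) {
    data.frame(chrom = "c", center_t0 = 1000L, center_t3 = 1000L,
               position_call = "unchanged", occupancy_call = occ,
               shift_bp = 0L, shift_direction = "none",
               stringsAsFactors = FALSE)
  }
  cons <- replicate_consensus(list(mk_rep("reduced"), mk_rep("reduced"),
                                   mk_rep("retained")))
  expect_identical(cons$consensus_occupancy, "none")
})

test_that("linking respects the 74 bp radius and replicate uniqueness", {
  r1 <- data.frame(chrom = "c", center_t0 = c(1000L, 1200L),
                   center_t3 = c(1000L, 1200L),
                   position_call = "unchanged", occupancy_call = "unchanged",
                   shift_bp = 0L, shift_direction = "none",
                   stringsAsFactors = FALSE)
  r2 <- data.frame(chrom = "c", center_t0 = c(1050L, 1400L),
                   center_t3 = c(1050L, 1400L),
                   position_call = "unchanged", occupancy_call = "unchanged",
                   shift_bp = 0L, shift_direction = "none",
                   stringsAsFactors = FALSE)
  cons <- replicate_consensus(list(r1, r2))
  # 1000+1050 link (within 74); 1200 and 1400 stay separate
  expect_identical(nrow(cons), 3L)
  expect_identical(cons$support, c(2L, 1L, 1L))
  expect_identical(cons$consensus_dyad[1L], 1025L)
})

test_that("depletion filtering is per attribute and counts categories", {
  mk_cons <- function(dyad, pos, occ) {
    data.frame(chrom = "c", consensus_dyad = as.integer(dyad),
               support = 2L, consensus_position = pos,
               consensus_occupancy = occ, stringsAsFactors = FALSE)
  }
  sh <- rbind(mk_cons(1000, "altered", "reduced"),
              mk_cons(2000, "altered", "unchanged"),
              mk_cons(3000, "unchanged", "reduced"))
  wt <- rbind(mk_cons(1010, "altered", "unchanged"),
              mk_cons(3050, "unchanged", "reduced"))
  dd <- depletion_dependent(sh, wt)
  # row 1: position altered matches wildtype -> not depletion dependent;
  #        occupancy reduced has no wildtype match -> depletion dependent
  expect_false(dd$position_depletion_dependent[1L])
  expect_true(dd$occupancy_depletion_dependent[1L])
  # row 2: altered, no matching wildtype altered nearby
  expect_true(dd$position_depletion_dependent[2L])
  # row 3: reduced matched in wildtype within 74 bp
  expect_false(dd$occupancy_depletion_dependent[3L])
  lc <- attr(dd, "label_counts")
  expect_true(is.data.frame(lc))
  red <- lc[lc$label == "reduced", ]
  expect_identical(red$shutoff_only, 1L)
  expect_identical(red$both, 1L)
})
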