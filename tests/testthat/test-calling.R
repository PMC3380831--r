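test_that("footprint_bounds follows the half-open convention", {
  fb <- footprint_bounds(1000L, 147L)
  expect_identical(fb$start, 927L)
  expect_identical(fb$end, 1001L + 73L)
  fb2 <- footprint_bounds(c(100L, 200L), c(146L, 147L))
  expect_identical(fb2$end - fb2$start, c(147L, 147L))
})

test_that("min_density default is three times the kernel maximum", {
  cs <- c(chrA = 2000L)
  ctr <- center_list(list(chrA = rep(1000L, 10L)), cs)
  sm <- smooth_track(center_density(ctr), sd = 10)
  frags <- data.frame(chrom = "chrA", start = 927L, end = 1074L,
                      stringsAsFactors = FALSE)
  # a 2-center peak is below 3 x kernel max, a 4-center peak is above
  ctr2 <- center_list(list(chrA = rep(1000L, 2L)), cs)
  sm2 <- smooth_track(center_density(ctr2), sd = 10)
  expect_identical(nrow(call_nucleosomes(sm2, ctr2, frags)), 0L)
  ctr4 <- center_list(list(chrA = rep(1000L, 4L)), cs)
  sm4 <- smooth_track(center_density(ctr4), sd = 10)
  expect_identical(nrow(call_nucleosomes(sm4, ctr4, frags)), 1L)
  # unsmoothed tracks demand an explicit threshold
  expect_error(call_nucleosomes(center_density(ctr), ctr, frags),
               "min_density")
})

test_that("a lone peak is called with correct summary statistics", {
  cs <- c(chrA = 2000L)
  centers <- c(rep(995L, 3L), rep(1000L, 4L), rep(1005L, 3L))
  ctr <- center_list(list(chrA = centers), cs)
  sm <- smooth_track(center_density(ctr), sd = 10)
  frags <- data.frame(chrom = "chrA",
                      start = centers - 73L, end = centers + 74L,
                      stringsAsFactors = FALSE)
  calls <- call_nucleosomes(sm, ctr, frags)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$center, 1000L)
  expect_identical(calls$protected_length, 147L)
  expect_identical(calls$n_members, 10L)
  expect_identical(calls$occupancy, 10L)
  expect_equal(calls$fuzziness, sd(centers))
  expect_equal(calls$member_mean, mean(centers))
})

test_that("ties resolve to the leftmost coordinate", {
  cs <- c(chrA = 3000L)
  # two identical, well-separated peaks: both called, left one first
  centers <- c(rep(1000L, 5L), rep(2000L, 5L))
  ctr <- center_list(list(chrA = centers), cs)
  sm <- smooth_track(center_density(ctr), sd = 10)
  frags <- data.frame(chrom = "chrA", start = centers - 73L,
                      end = centers + 74L, stringsAsFactors = FALSE)
  calls <- call_nucleosomes(sm, ctr, frags)
  calls <- calls[order(calls$call_rank), ]
  expect_identical(calls$center, c(1000L, 2000L))
})

test_that("protected length falls back when no fragment covers the center", {
  cs <- c(chrA = 2000L)
  ctr <- center_list(list(chrA = rep(1000L, 5L)), cs)
  sm <- smooth_track(center_density(ctr), sd = 10)
  no_cover <- data.frame(chrom = "chrA", start = 1500L, end = 1647L,
                         stringsAsFactors = FALSE)
  calls <- call_nucleosomes(sm, ctr, no_cover, fallback_length = 151L)
  expect_identical(calls$protected_length, 151L)
})

test_that("zeroing prevents a second call inside the protected region", {
  cs <- c(chrA = 2000L)
  centers <- c(rep(1000L, 10L), rep(1030L, 9L))
  ctr <- center_list(list(chrA = centers), cs)
  sm <- smooth_track(center_density(ctr), sd = 10)
  frags <- data.frame(chrom = "chrA", start = centers - 73L,
                      end = centers + 74L, stringsAsFactors = FALSE)
  calls <- call_nucleosomes(sm, ctr, frags)
  # the secondary peak at 1030 lies inside 1000 +/- 73 and must not recur
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$center, 1000L)
})

test_that("caller equals the brute-force oracle on small synthetic tracks", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    n_nuc <- 8L
    dy <- sort(sample(100:1900, n_nuc))
    centers <- unlist(lapply(dy, function(d) {
      d + round(rnorm(rpois(1, 40), 0, 10))
    }))
    centers <- centers[centers >= 0L & centers < 2000L]
    len <- pmin(pmax(round(rnorm(length(centers), 147, 15)), 100L), 200L)
    frags <- data.frame(chrom = "chrTest",
                        start = as.integer(centers - len %/% 2L),
                        end = as.integer(centers - len %/% 2L + len),
                        stringsAsFactors = FALSE)
    res <- run_both_callers(2000L, as.integer(centers), frags)
    expect_gt(nrow(res$got), 0L)
    expect_identical(nrow(res$got), nrow(res$want))
    expect_identical(res$got$center, res$want$center)
    expect_identical(res$got$protected_length, res$want$protected_length)
    expect_identical(res$got$n_members, res$want$n_members)
    expect_identical(res$got$occupancy, res$want$occupancy)
    expect_equal(res$got$fuzziness, res$want$fuzziness, tolerance = 1e-10)
    expect_equal(res$got$member_mean, res$want$member_mean,
                 tolerance = 1e-10)
    expect_equal(res$got$peak_density, res$want$peak_density,
                 tolerance = 1e-12)
  }
})

test_that("adjacent call centers respect the zeroed-region spacing", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  f <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  ctr <- reads_to_centers(f, lay$chrom_sizes, mode = "paired")
  sm <- smooth_track(center_density(ctr), sd = 10)
  calls <- call_nucleosomes(sm, ctr, f)
  d <- diff(calls$center)
  minpl <- pmin(utils::head(calls$protected_length, -1),
                utils::tail(calls$protected_length, -1))
  expect_true(all(d > minpl %/% 2L))
})

test_that("max_calls caps the greedy sequence at the strongest peaks", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  f <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  ctr <- reads_to_centers(f, lay$chrom_sizes, mode = "paired")
  sm <- smooth_track(center_density(ctr), sd = 10)
  all_calls <- call_nucleosomes(sm, ctr, f)
  few <- call_nucleosomes(sm, ctr, f, max_calls = 10L)
  expect_identical(nrow(few), 10L)
  top <- all_calls[order(-all_calls$peak_density), ][1:10, ]
  expect_setequal(few$center, top$center)
})

test_that("member_centers returns the centers inside each footprint", {
  cs <- c(chrA = 2000L)
  centers <- c(900L, 950L, 1000L, 1050L, 1100L)
  ctr <- center_list(list(chrA = centers), cs)
  calls <- data.frame(chrom = "chrA", center = 1000L,
                      protected_length = 147L, stringsAsFactors = FALSE)
  mem <- member_centers(calls, ctr)
  expect_identical(mem[[1L]], c(950L, 1000L, 1050L))
})

test_that("calls round-trip through write_calls/read_calls", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  f <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  ctr <- reads_to_centers(f, lay$chrom_sizes, mode = "paired")
  sm <- smooth_track(center_density(ctr), sd = 10)
  calls <- call_nucleosomes(sm, ctr, f)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path, centers = ctr)
  back <- read_calls(path)
  expect_identical(back$center, calls$center)
  expect_identical(back$protected_length, calls$protected_length)
  expect_identical(back$occupancy, calls$occupancy)
  expect_equal(back$fuzziness, calls$fuzziness, tolerance = 1e-9)
  mem <- attr(back, "member_centers")
  expect_identical(length(mem), nrow(calls))
  expect_identical(mem[[1L]],
                   member_centers(calls, ctr)[[1L]])
})

test_that("read_calls reports malformed files clearly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tcenter", "chrA\t100"), path)
  expect_error(read_calls(path), "protected_length")
})
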