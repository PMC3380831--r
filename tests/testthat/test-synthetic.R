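test_that("sim_config validates its inputs", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$spacing_mean, 165L)
  expect_error(sim_config(reduce_fraction = -0.1), "reduce_fraction")
  expect_error(sim_config(reduce_fraction = 0.6, retain_fraction = 0.3,
                          shift_fraction = 0.3), "exceed")
  expect_error(sim_config(reduce_factor = 1.2), "reduce_factor")
  expect_error(sim_config(retain_factor = 0.5), "retain_factor")
})

test_that("read_sim_config round-trips a flat key=value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("seed=9", "chrom_length=40000", "background_fraction=0.1",
               "paired=FALSE"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$seed, 9L)
  expect_identical(cfg$chrom_length, 40000L)
  expect_equal(cfg$background_fraction, 0.1)
  expect_false(cfg$paired)
})

test_that("generate_layout tiles non-overlapping genes with promoters", {
  cfg <- sim_config(seed = 2, n_chroms = 2L, chrom_length = 1e5L,
                    n_genes = 20L)
  lay <- generate_layout(cfg)
  expect_identical(names(lay$chrom_sizes), c("chr01", "chr02"))
  expect_identical(nrow(lay$genes), 40L)
  for (cc in names(lay$chrom_sizes)) {
    g <- lay$genes[lay$genes$chrom == cc, ]
    expect_true(all(g$start < g$end))
    expect_true(all(g$end <= lay$chrom_sizes[[cc]]))
    expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
  }
  # promoters end where their gene starts and do not overlap it
  expect_identical(lay$promoters$end, lay$genes$start)
  expect_true(all(lay$promoters$start < lay$promoters$end))
  # TSS matches strand orientation
  plus <- lay$genes$strand == "+"
  expect_identical(lay$genes$tss[plus], lay$genes$start[plus])
  expect_identical(lay$genes$tss[!plus], lay$genes$end[!plus] - 1L)
})

test_that("generate_layout handles a gene-free genome", {
  lay <- generate_layout(sim_config(n_genes = 0L))
  expect_identical(nrow(lay$genes), 0L)
  expect_identical(nrow(lay$promoters), 0L)
})

test_that("generate_layout rejects overcrowded genomes", {
  expect_error(generate_layout(sim_config(chrom_length = 1000L,
                                          n_genes = 10L)), "slot")
})

test_that("plant_truth places a jittered grid with configured labels", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  expect_s3_class(tr, "sim_truth")
  # grid spacing stays near spacing_mean despite +/- jitter
  d <- diff(tr$dyad_t0)
  expect_true(all(d >= cfg$spacing_mean - 2L * cfg$jitter))
  expect_true(all(d <= cfg$spacing_mean + 2L * cfg$jitter))
  expect_true(all(tr$dyad_t0 >= 74L))
  expect_true(all(tr$dyad_t0 <= cfg$chrom_length - 75L))
  expect_setequal(unique(tr$label),
                  c("stable", "reduced", "retained", "shifted"))
  # weight invariants per label
  red <- tr$label == "reduced"
  expect_equal(tr$weight_t3[red], cfg$reduce_factor * tr$weight_t0[red])
  ret <- tr$label == "retained"
  expect_equal(tr$weight_t3[ret], cfg$retain_factor * tr$weight_t0[ret])
  stab <- tr$label == "stable"
  expect_identical(tr$weight_t3[stab], tr$weight_t0[stab])
  expect_identical(tr$dyad_t3[stab], tr$dyad_t0[stab])
  shf <- tr$label == "shifted"
  expect_true(all(abs(tr$dyad_t3[shf] - tr$dyad_t0[shf]) ==
                    cfg$shift_magnitude))
})

test_that("plant_truth is deterministic in the config seed", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  expect_identical(plant_truth(lay, cfg), plant_truth(lay, cfg))
})

test_that("promoter bias concentrates reduced labels in promoters", {
  cfg <- sim_config(seed = 3, n_chroms = 4L, chrom_length = 1e5L,
                    n_genes = 20L, reduce_fraction = 0.1)
  lay <- generate_layout(cfg)
  tr_bias <- plant_truth(lay, cfg)
  cfg_no <- sim_config(seed = 3, n_chroms = 4L, chrom_length = 1e5L,
                       n_genes = 20L, reduce_fraction = 0.1,
                       promoter_bias = FALSE)
  tr_no <- plant_truth(generate_layout(cfg_no), cfg_no)
  in_prom <- function(tr) {
    red <- tr$label == "reduced"
    hit <- dyadcall:::points_in_intervals(tr$chrom[red], tr$dyad_t0[red],
                                          lay$promoters)
    mean(hit)
  }
  expect_gt(in_prom(tr_bias), in_prom(tr_no))
})

test_that("simulate_fragments respects weights, lengths and determinism", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  f1 <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  f2 <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  expect_identical(f1, f2)
  f3 <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 2L)
  expect_false(identical(f1, f3))

  # spans are clipped to the chromosome at the edges, so only interior
  # fragments carry the full sampled length
  len <- f1$end - f1$start
  interior <- f1$start > 0L & f1$end < cfg$chrom_length
  expect_true(all(len[interior] >= 100L & len[interior] <= 200L))
  expect_true(all(len <= 200L))
  expect_true(all(f1$start >= 0L))
  expect_true(all(f1$end <= cfg$chrom_length))
  # total depth close to expectation (per-nucleosome reads + background)
  expected <- sum(tr$weight_t0) * cfg$reads_per_nucleosome_mean /
    (1 - cfg$background_fraction)
  expect_lt(abs(nrow(f1) / expected - 1), 0.05)
})

test_that("reduced nucleosomes lose fragments at 3 h", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  fr <- sim_replicate(tr, lay, cfg)
  count_near <- function(frags, dyads) {
    mid <- frags$start + (frags$end - frags$start) %/% 2L
    vapply(dyads, function(d) sum(abs(mid - d) <= 50L), numeric(1))
  }
  red <- tr$label == "reduced"
  n0 <- count_near(fr$t0, tr$dyad_t0[red])
  n3 <- count_near(fr$t3, tr$dyad_t3[red])
  expect_lt(sum(n3), 0.7 * sum(n0))
})

test_that("single-end mode emits fixed-length stranded reads", {
  cfg <- small_config(paired = FALSE)
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  f <- simulate_fragments(tr, lay, "t0", cfg, replicate_seed = 1L)
  expect_true(all(f$end - f$start == cfg$read_length))
  expect_setequal(unique(f$strand), c("+", "-"))
})

test_that("simulate_call_table matches the planted truth layout", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  ct <- simulate_call_table(tr, cfg, "t0", replicate_seed = 1L)
  expect_true(all(c("center", "occupancy", "n_members", "member_mean",
                    "member_var", "truth_row") %in% names(ct)))
  # centers land near their planted dyads
  expect_true(all(abs(ct$center - tr$dyad_t0[ct$truth_row]) <= 10L))
  # occupancy counts the members within +/- 50 bp, so occupancy <= members
  expect_true(all(ct$occupancy <= ct$n_members))
  expect_identical(ct, simulate_call_table(tr, cfg, "t0", replicate_seed = 1L))
})

test_that("annotation track carries the planted class effect", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  at <- generate_annotation_track(tr, lay, "reduced", effect_size = 2,
                                  seed = 4)
  red <- tr$label == "reduced"
  expect_gt(mean(at$scores[red]) - mean(at$scores[!red]), 1)
  # rasterised footprint values equal the per-nucleosome scores
  i <- which(red)[1L]
  v <- at$track$values[[tr$chrom[i]]]
  expect_equal(v[tr$dyad_t0[i] + 1L], at$scores[i])
})

test_that("coarse annotation resolution produces constant bins", {
  cfg <- small_config()
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  at <- generate_annotation_track(tr, lay, "stable", resolution = 50L,
                                  seed = 4)
  v <- at$track$values[[1L]]
  bin <- v[1:50]
  expect_true(all(is.na(bin)) || length(unique(bin[!is.na(bin)])) <= 1L)
})

test_that("expression classes couple to promoter-reduced nucleosomes", {
  cfg <- sim_config(seed = 6, n_chroms = 4L, chrom_length = 1e5L,
                    n_genes = 20L, reduce_fraction = 0.15)
  lay <- generate_layout(cfg)
  tr <- plant_truth(lay, cfg)
  cls <- assign_expression_classes(lay, tr, coupling = 1, seed = 2)
  red <- tr[tr$label == "reduced", ]
  hit <- vapply(seq_len(nrow(lay$promoters)), function(i) {
    any(red$chrom == lay$promoters$chrom[i] &
          red$dyad_t0 >= lay$promoters$start[i] &
          red$dyad_t0 < lay$promoters$end[i])
  }, logical(1))
  coupled_genes <- lay$promoters$gene_id[hit]
  expect_true(all(cls$class[cls$gene_id %in% coupled_genes] == "increased"))
})
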