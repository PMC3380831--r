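#' Process one replicate end to end
#'
#' Fragments from the two time points are converted to read centers
#' (estimating the fragment length from strand cross-correlation in
#' single-end mode), filtered against excluded regions, depth-normalised
#' by subsampling both time points to a common number of centers,
#' smoothed, called, paired, and classified.
#'
#' @param frags_t0,frags_t3 Fragment data.frames (see
#'   [simulate_fragments()] / [read_fragments_bed()]).
#' @param chrom_sizes Named integer vector.
#' @param paired Logical; paired fragments or single-end reads.
#' @param excluded Optional excluded-interval data.frame.
#' @param subsample_n Common depth; default `min` of the two libraries.
#' @param smooth_sd Smoothing s.d. (bp).
#' @param min_density Caller termination threshold (default: see
#'   [call_nucleosomes()]).
#' @param thresholds A [classification_thresholds()] object.
#' @param anchor Occupancy window anchor (see [classify_pairs()]).
#' @param seed Seed for the depth subsampling.
#' @return A list: `calls_t0`, `calls_t3`, `centers_t0`, `centers_t3`,
#'   `classification` (a [classify_pairs()] result), and
#'   `fragment_length` (single-end estimate, else `NA`).
#' @export
analyze_replicate <- function(frags_t0, frags_t3, chrom_sizes, paired = TRUE,
                              excluded = NULL, subsample_n = NULL,
                              smooth_sd = 10, min_density = NULL,
                              thresholds = classification_thresholds(),
                              anchor = "consensus", seed = 1L) {
  one_tp <- function(frags) {
    if (paired) {
      fl <- NA_integer_
      ctr <- reads_to_centers(frags, chrom_sizes, mode = "paired")
      ext <- frags
    } else {
      fl <- estimate_fragment_length(frags)
      ctr <- reads_to_centers(frags, chrom_sizes, mode = "single",
                              fragment_length = fl)
      ext <- extend_reads(frags, chrom_sizes, fl)
    }
    if (!is.null(excluded) && nrow(excluded)) {
      ctr <- filter_excluded(ctr, excluded)
    }
    list(centers = ctr, extended = ext, fragment_length = fl)
  }
  a <- one_tp(frags_t0)
  b <- one_tp(frags_t3)
  n_common <- if (is.null(subsample_n)) {
    min(n_centers(a$centers), n_centers(b$centers))
  } else subsample_n
  a$centers <- subsample_centers(a$centers, n_common, seed = seed)
  b$centers <- subsample_centers(b$centers, n_common, seed = seed + 1L)

  call_tp <- function(x) {
    sm <- smooth_track(center_density(x$centers), sd = smooth_sd)
    call_nucleosomes(sm, x$centers, x$extended, min_density = min_density)
  }
  calls_t0 <- call_tp(a)
  calls_t3 <- call_tp(b)
  pairs <- pair_calls(calls_t0, calls_t3, thresholds)
  cls <- classify_pairs(pairs, a$centers, b$centers,
                        thresholds = thresholds, anchor = anchor)
  list(calls_t0 = calls_t0, calls_t3 = calls_t3,
       centers_t0 = a$centers, centers_t3 = b$centers,
       classification = cls,
       fragment_length = a$fragment_length)
}

#' Run a multi-replicate experiment on simulated truth
#'
#' Simulates `n_replicates` fragment libraries per time point from one
#' planted truth, analyses each replicate with [analyze_replicate()],
#' and builds the cross-replicate consensus.
#'
#' @param truth A [plant_truth()] result.
#' @param layout The matching layout.
#' @param config A [sim_config()] object.
#' @param seed_offset Added to each replicate's seed (keeps strains /
#'   experiments independent).
#' @param ... Passed to [analyze_replicate()].
#' @return A list: `replicates` (per-replicate [analyze_replicate()]
#'   results) and `consensus` (a [replicate_consensus()] result).
#' @export
analyze_experiment <- function(truth, layout, config, seed_offset = 0L, ...) {
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    rs <- r + seed_offset
    f0 <- simulate_fragments(truth, layout, "t0", config, replicate_seed = rs)
    f3 <- simulate_fragments(truth, layout, "t3", config, replicate_seed = rs)
    analyze_replicate(f0, f3, layout$chrom_sizes, paired = config$paired,
                      seed = rs, ...)
  })
  cls <- lapply(reps, `[[`, "classification")
  list(replicates = reps, consensus = replicate_consensus(cls))
}

#' Match consensus nucleosomes to planted truth
#'
#' Greedy nearest-dyad matching of consensus nucleosomes to planted 0 h
#' dyads within `radius` bp.
#'
#' @param consensus A [replicate_consensus()] result.
#' @param truth A `sim_truth` data.frame.
#' @param radius Match radius (bp).
#' @return Integer vector: for each truth row, the matching consensus
#'   row index or `NA`.
#' @export
match_truth <- function(consensus, truth, radius = 74L) {
  out <- rep(NA_integer_, nrow(truth))
  for (cc in unique(truth$chrom)) {
    ti <- which(truth$chrom == cc)
    ci <- which(consensus$chrom == cc)
    if (!length(ci)) next
    for (i in ti) {
      j <- ci[which.min(abs(consensus$consensus_dyad[ci] - truth$dyad_t0[i]))]
      if (abs(consensus$consensus_dyad[j] - truth$dyad_t0[i]) <= radius) {
        out[i] <- j
      }
    }
  }
  out
}
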