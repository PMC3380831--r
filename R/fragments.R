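#' Simulate MNase-like fragments from a planted nucleosome map
#'
#' For each planted nucleosome at the requested time point, a
#' Poisson(`weight * reads_per_nucleosome_mean`) number of fragments is
#' drawn; each fragment midpoint is the dyad plus rounded
#' Normal(0, `fuzziness_sd`) noise, and each length is rounded
#' Normal(`fragment_mean`, `fragment_sd`), clipped to 100-200 bp in
#' paired mode (so simulated fragments survive the pairing filter).  A
#' further `background_fraction` of all fragments get uniform random
#' midpoints, strand-balanced, allocated across chromosomes in proportion
#' to length.  In single-end mode one strand-bearing read of
#' `read_length` bp is emitted from a uniformly chosen fragment end.
#'
#' @param truth A [plant_truth()] result.
#' @param layout The matching [generate_layout()] result.
#' @param timepoint `"t0"` or `"t3"`.
#' @param config A [sim_config()] object.
#' @param replicate_seed Integer; replicates differ only by this seed, the
#'   biological truth is shared.
#' @return A data.frame of fragment records: `chrom`, `start`, `end`
#'   (0-based, half-open), `strand` (`"+"`/`"-"`, or `"."` for paired
#'   fragments), `paired`.  Sorted by chromosome and start.
#' @export
simulate_fragments <- function(truth, layout, timepoint = c("t0", "t3"),
                               config, replicate_seed = 1L) {
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(truth, "data.frame"), inherits(config, "sim_config"))
  withr::local_seed(2L * as.integer(replicate_seed) +
                      (timepoint == "t3") + 10L * config$seed)

  w <- if (timepoint == "t0") truth$weight_t0 else truth$weight_t3
  dy <- if (timepoint == "t0") truth$dyad_t0 else truth$dyad_t3
  counts <- rpois(nrow(truth), w * config$reads_per_nucleosome_mean)
  n_nuc <- sum(counts)

  mid <- rep(dy, counts) + as.integer(round(rnorm(n_nuc, 0, config$fuzziness_sd)))
  chrom <- rep(truth$chrom, counts)

  # background: uniform midpoints, chromosomes in proportion to length
  bf <- config$background_fraction
  n_bg <- if (bf > 0) as.integer(round(n_nuc * bf / (1 - bf))) else 0L
  if (n_bg > 0L) {
    sizes <- layout$chrom_sizes
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
    bg_mid <- as.integer(floor(runif(n_bg) * sizes[bg_chrom]))
    mid <- c(mid, bg_mid)
    chrom <- c(chrom, bg_chrom)
  }
  n <- length(mid)

  lens <- as.integer(round(rnorm(n, config$fragment_mean, config$fragment_sd)))
  if (config$paired) lens <- pmin(pmax(lens, 100L), 200L)
  lens <- pmax(lens, 1L)

  start <- mid - lens %/% 2L
  end <- start + lens
  clen <- unname(layout$chrom_sizes[chrom])
  start <- pmax(start, 0L)
  end <- pmin(end, clen)
  keep <- start < end
  start <- start[keep]; end <- end[keep]; chrom <- chrom[keep]
  n <- length(start)

  if (config$paired) {
    out <- data.frame(chrom = chrom, start = start, end = end, strand = ".",
                      paired = TRUE, stringsAsFactors = FALSE)
  } else {
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rl <- config$read_length
    r_start <- ifelse(strand == "+", start, pmax(end - rl, start))
    r_end <- ifelse(strand == "+", pmin(start + rl, end), end)
    out <- data.frame(chrom = chrom, start = as.integer(r_start),
                      end = as.integer(r_end), strand = strand,
                      paired = FALSE, stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate per-replicate nucleosome call tables directly from truth
#'
#' Fast path that emulates the distribution of the caller's output without
#' simulating fragments: for each planted nucleosome a Poisson number of
#' member read centers is drawn around the dyad, and the per-call summary
#' statistics the classifier consumes (center, member mean/variance,
#' occupancy within +/-50 bp) are computed from those draws.  Used for
#' large-scale calibration studies where running the full caller on a
#' multi-megabase genome would dominate runtime; the full fragment-level
#' path is exercised separately.
#'
#' @inheritParams simulate_fragments
#' @return A calls data.frame compatible with [pair_calls()].
#' @export
simulate_call_table <- function(truth, config, timepoint = c("t0", "t3"),
                                replicate_seed = 1L) {
  timepoint <- match.arg(timepoint)
  withr::local_seed(1000L + 2L * as.integer(replicate_seed) +
                      (timepoint == "t3") + 10L * config$seed)
  w <- if (timepoint == "t0") truth$weight_t0 else truth$weight_t3
  dy <- if (timepoint == "t0") truth$dyad_t0 else truth$dyad_t3
  counts <- rpois(nrow(truth), w * config$reads_per_nucleosome_mean)
  keep <- counts > 0L
  n_mem <- counts[keep]
  x <- rep(dy[keep], n_mem) + round(rnorm(sum(n_mem), 0, config$fuzziness_sd))
  # groups are contiguous runs, so segment sums via cumsum
  ends <- cumsum(n_mem)
  starts <- ends - n_mem + 1L
  seg_sum <- function(z) {
    cs <- cumsum(z)
    cs[ends] - c(0, cs[head(ends, -1L)])
  }
  # moments relative to the planted dyad for numerical stability
  xr <- x - rep(dy[keep], n_mem)
  s1 <- seg_sum(xr)
  s2 <- seg_sum(xr * xr)
  m <- dy[keep] + s1 / n_mem
  v <- ifelse(n_mem > 1L, (s2 - s1^2 / n_mem) / (n_mem - 1L), 0)
  v <- pmax(v, 0)
  center <- as.integer(round(m))
  # occupancy: members within +/-50 bp of the call center
  occ <- as.integer(seg_sum(abs(x - rep(center, n_mem)) <= 50L))
  out <- data.frame(
    chrom = truth$chrom[keep], center = center,
    protected_length = config$fragment_mean,
    fuzziness = sqrt(v), occupancy = occ, n_members = n_mem,
    member_mean = m, member_var = v,
    truth_row = seq_len(nrow(truth))[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$center), , drop = FALSE]
  rownames(out) <- NULL
  out
}
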