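# Literal reference implementations used as oracles.

# Brute-force greedy caller (one chromosome): repeat
#   1) leftmost maximum of the smoothed density = center
#   2) protected length = rounded mean length of fragments covering it
#   3) fuzziness = sd of read centers in the protected region
#   4) zero density on center +/- floor(protected/2)
#   5) occupancy = read centers within +/- occ_halfwin
# until the maximum drops below min_density.
oracle_call_chrom <- function(dens, centers, frag_start, frag_end,
                              min_density, fallback_len = 147L,
                              occ_halfwin = 50L, max_calls = Inf) {
  n <- length(dens)
  cnt <- tabulate(centers + 1L, nbins = n)
  rows <- list()
  while (length(rows) < max_calls) {
    best <- max(dens)
    if (best < min_density || best <= 0) break
    c0 <- which(dens == best)[1L] - 1L
    cover <- frag_start <= c0 & frag_end > c0
    pl <- if (any(cover)) {
      max(as.integer(round(mean((frag_end - frag_start)[cover]))), 1L)
    } else as.integer(fallback_len)
    half <- pl / 2
    mlo <- max(as.integer(ceiling(c0 - half)), 0L)
    mhi <- min(as.integer(floor(c0 + half)), n - 1L)
    mem <- rep(mlo:mhi, cnt[(mlo:mhi) + 1L])
    n_mem <- length(mem)
    olo <- max(c0 - occ_halfwin, 0L); ohi <- min(c0 + occ_halfwin, n - 1L)
    occ <- sum(cnt[(olo:ohi) + 1L])
    zlo <- max(c0 - pl %/% 2L, 0L); zhi <- min(c0 + pl %/% 2L, n - 1L)
    dens[(zlo:zhi) + 1L] <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      center = c0, protected_length = pl,
      fuzziness = if (n_mem >= 2L) stats::sd(mem) else 0,
      occupancy = occ, n_members = n_mem,
      member_mean = if (n_mem) mean(mem) else as.numeric(c0),
      peak_density = best)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Run the installed caller and the oracle on the same inputs and return
# both tables sorted by greedy order (the caller sorts by coordinate, so
# resort by call_rank).
run_both_callers <- function(chrom_len, centers, frags, sd = 10,
                             min_density = NULL, fallback_len = 147L) {
  cs <- c(chrTest = as.integer(chrom_len))
  cl <- center_list(list(chrTest = centers), cs)
  sm <- smooth_track(center_density(cl), sd = sd)
  if (is.null(min_density)) {
    min_density <- 3 * max(gaussian_kernel(sd, 3))
  }
  got <- call_nucleosomes(sm, cl, frags, min_density = min_density,
                          fallback_length = fallback_len)
  got <- got[order(got$call_rank), , drop = FALSE]
  fr <- frags[frags$chrom == "chrTest", , drop = FALSE]
  want <- oracle_call_chrom(sm$values$chrTest, cl$centers$chrTest,
                            fr$start, fr$end, min_density,
                            fallback_len = fallback_len)
  list(got = got, want = want)
}

# Exact binomial tail probabilities via log binomial coefficients.
oracle_binom_lower <- function(k, n) {
  vapply(seq_along(k), function(i) {
    if (n[i] == 0L) return(1)
    j <- 0:min(k[i], n[i])
    if (k[i] < 0L) return(0)
    sum(exp(lchoose(n[i], j) - n[i] * log(2)))
  }, numeric(1))
}

oracle_binom_upper <- function(k, n) {
  # P(X >= k) for X ~ Bin(n, 1/2)
  vapply(seq_along(k), function(i) {
    if (k[i] > n[i]) return(0)
    j <- max(k[i], 0L):n[i]
    sum(exp(lchoose(n[i], j) - n[i] * log(2)))
  }, numeric(1))
}

# Brute-force footprint mean of a track over center +/- floor(len/2).
oracle_score <- function(track, chrom, center, len) {
  vapply(seq_along(center), function(i) {
    v <- track$values[[chrom[i]]]
    half <- len[i] %/% 2L
    lo <- max(center[i] - half, 0L); hi <- min(center[i] + half,
                                               length(v) - 1L)
    w <- v[(lo:hi) + 1L]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}
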