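#' Footprint bounds of a nucleosome call
#'
#' The protected footprint is represented half-open as
#' `[center - floor(L/2), center + floor(L/2) + 1)`, matching the BED
#' export convention (147 bp footprint spans `center - 73` to
#' `center + 74`).
#'
#' @param center Integer vector of call centers (0-based).
#' @param protected_length Integer vector of protected lengths (bp).
#' @return A list with integer vectors `start` and `end`.
#' @export
footprint_bounds <- function(center, protected_length) {
  half <- protected_length %/% 2L
  list(start = center - half, end = center + half + 1L)
}

#' Call nucleosomes by iterative greedy peak detection
#'
#' Repeats, per chromosome: (1) the maximum of the remaining smoothed
#' read-center density becomes a nucleosome center (ties resolved to the
#' leftmost coordinate); (2) the protected length is the rounded mean
#' length of all fragments covering the center base (falling back to
#' `fallback_length` when none do); (3) fuzziness is the sample s.d. of
#' read centers within the protected region; (4) the smoothed density on
#' `center +/- floor(protected/2)` is zeroed so overlapping nucleosomes
#' cannot be called; (5) occupancy is the number of read centers within
#' 50 bp on either side of the center.  Calling stops when the remaining
#' maximum falls below `min_density` or `max_calls` is reached.
#'
#' The caller is fully deterministic.  Because zeroing is confined to a
#' chromosome, per-chromosome greedy sequences are independent and the
#' genome-wide call set equals that of a single global greedy pass.
#'
#' @param smoothed A smoothed `density_track` (see [smooth_track()]).
#' @param centers The [center_list()] the track was built from.
#' @param reads Fragment data.frame (`chrom`, `start`, `end`) used for
#'   protected-length computation; single-end reads should be extended
#'   with [extend_reads()] first.
#' @param min_density Termination threshold on the smoothed density.
#'   Defaults to the peak height of 3 co-located centers (3 x kernel
#'   maximum): weaker peaks cannot survive the downstream >5-read
#'   coverage filter anyway.
#' @param max_calls Optional cap on the number of calls.
#' @param fallback_length Protected length used when no fragment covers
#'   the center base (bp).
#' @param occ_halfwin Occupancy half-window (bp).
#' @return A data.frame of class `nucleosome_calls`, sorted by
#'   coordinate: `chrom`, `center`, `protected_length`, `fuzziness`,
#'   `occupancy`, `n_members`, `member_mean`, `member_var`,
#'   `peak_density`, `call_rank` (per-chromosome greedy order).
#' @export
call_nucleosomes <- function(smoothed, centers, reads, min_density = NULL,
                             max_calls = NULL, fallback_length = 147L,
                             occ_halfwin = 50L) {
  if (is.null(min_density)) {
    if (is.na(smoothed$kernel_window) || smoothed$smoothing_sd <= 0) {
      stop("`min_density` must be given explicitly for an unsmoothed track",
           call. = FALSE)
    }
    min_density <- 3 * max(gaussian_kernel(smoothed$smoothing_sd,
                                           smoothed$kernel_window))
  }
  if (is.null(max_calls)) max_calls <- 0L  # 0 = unlimited in the kernel

  res <- vector("list", length(smoothed$values))
  chroms <- names(smoothed$values)
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    v <- smoothed$values[[cc]]
    n <- length(v)
    cnt <- tabulate(centers$centers[[cc]] + 1L, nbins = n)
    r <- reads[reads$chrom == cc, , drop = FALSE]
    dcnt <- numeric(n + 1L)
    dsum <- numeric(n + 1L)
    if (nrow(r) > 0L) {
      rs <- pmax(r$start, 0L); re <- pmin(r$end, n)
      rl <- as.numeric(r$end - r$start)
      dt <- data.table(pos = c(rs, re), w = c(rep(1, length(rs)), -rep(1, length(re))),
                       wl = c(rl, -rl))
      agg <- dt[, list(w = sum(w), wl = sum(wl)), by = pos]
      dcnt[agg$pos + 1L] <- agg$w
      dsum[agg$pos + 1L] <- agg$wl
    }
    cov_cnt <- cumsum(dcnt)[seq_len(n)]
    cov_sumlen <- cumsum(dsum)[seq_len(n)]
    out <- greedy_call_chrom(v, cnt, cov_cnt, cov_sumlen, min_density,
                             as.integer(max_calls), as.integer(fallback_length),
                             as.integer(occ_halfwin))
    if (length(out$center)) {
      res[[i]] <- data.frame(chrom = cc, center = out$center,
                             protected_length = out$protected_length,
                             fuzziness = out$fuzziness,
                             occupancy = out$occupancy,
                             n_members = out$n_members,
                             member_mean = out$member_mean,
                             member_var = out$fuzziness^2,
                             peak_density = out$peak_density,
                             call_rank = seq_along(out$center),
                             stringsAsFactors = FALSE)
    }
  }
  res <- res[!vapply(res, is.null, TRUE)]
  calls <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), center = integer(),
               protected_length = integer(), fuzziness = numeric(),
               occupancy = integer(), n_members = integer(),
               member_mean = numeric(), member_var = numeric(),
               peak_density = numeric(), call_rank = integer(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$center), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("nucleosome_calls", "data.frame")
  calls
}

#' Materialise member read centers for each call
#'
#' Returns, for each call, the coordinates of read centers falling within
#' its protected region (`center +/- protected_length / 2`), with
#' multiplicity.
#'
#' @param calls A `nucleosome_calls` data.frame.
#' @param centers The [center_list()] used for calling.
#' @return A list of integer vectors, one per call.
#' @export
member_centers <- function(calls, centers) {
  lapply(seq_len(nrow(calls)), function(i) {
    x <- centers$centers[[calls$chrom[i]]]
    half <- calls$protected_length[i] / 2
    x[abs(x - calls$center[i]) <= half]
  })
}
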