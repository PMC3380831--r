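#' Normalised log2 nucleosome occupancy track
#'
#' Smooths the per-base read-center counts (Gaussian, default s.d.
#' 10 bp), divides by the genome-wide mean and takes log2 with a
#' pseudocount equal to the smoothed track's 1st percentile (falling
#' back to 1% of the mean when that percentile is zero).  A uniform
#' library maps to 0 everywhere, and rescaling all counts leaves the
#' track unchanged.
#'
#' @param centers A depth-normalised [center_list()].
#' @param sd Smoothing s.d. (bp).
#' @param pseudocount Override for the additive pseudocount.
#' @return An `annotation_track` of log2 normalised occupancy with
#'   attributes `pseudocount` and `genome_mean`.
#' @export
occupancy_track <- function(centers, sd = 10, pseudocount = NULL) {
  if (n_centers(centers) == 0L) stop("empty center list", call. = FALSE)
  sm <- smooth_track(center_density(centers), sd = sd)
  all_v <- unlist(sm$values, use.names = FALSE)
  if (is.null(pseudocount)) {
    pseudocount <- quantile(all_v, 0.01, names = FALSE)
    if (pseudocount <= 0) pseudocount <- 0.01 * mean(all_v)
  }
  mu <- mean(all_v) + pseudocount
  vals <- lapply(sm$values, function(v) log2((v + pseudocount) / mu))
  structure(list(values = vals, resolution = 1L),
            class = "annotation_track",
            pseudocount = pseudocount,
            genome_mean = mean(all_v))
}

#' Genome-wide correlation of two tracks
#'
#' Pearson correlation over every `stride`-th position where both tracks
#' are defined.
#'
#' @param track_a,track_b Tracks over the same genome.
#' @param stride Position subsampling step (bp).
#' @return Pearson r.
#' @export
trackwise_correlation <- function(track_a, track_b, stride = 1L) {
  xs <- list(); ys <- list()
  for (cc in names(track_a$values)) {
    a <- track_a$values[[cc]]
    b <- track_b$values[[cc]]
    if (is.null(b)) next
    n <- min(length(a), length(b))
    idx <- seq.int(1L, n, by = stride)
    a <- a[idx]; b <- b[idx]
    ok <- !is.na(a) & !is.na(b)
    xs[[cc]] <- a[ok]; ys[[cc]] <- b[ok]
  }
  x <- unlist(xs, use.names = FALSE)
  y <- unlist(ys, use.names = FALSE)
  if (length(x) < 2L) stop("fewer than 2 shared positions", call. = FALSE)
  cor(x, y)
}

# footprint-mean of a track at an arbitrary position, fixed window length
window_mean <- function(track, chrom, center, wlen) {
  out <- rep(NA_real_, length(center))
  half <- wlen %/% 2L
  for (cc in unique(chrom)) {
    v <- track$values[[cc]]
    if (is.null(v)) next
    n <- length(v)
    cs_val <- cumsum(c(0, ifelse(is.na(v), 0, v)))
    cs_n <- cumsum(c(0, !is.na(v)))
    sel <- which(chrom == cc)
    lo <- pmax(center[sel] - half[sel], 0L)
    hi <- pmin(center[sel] + half[sel], n - 1L)
    cnt <- cs_n[hi + 2L] - cs_n[lo + 1L]
    tot <- cs_val[hi + 2L] - cs_val[lo + 1L]
    out[sel] <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  out
}

#' Change in sequence-predicted occupancy along a position shift
#'
#' For each pair, the footprint-mean preference score at the 3 h center
#' minus that at the 0 h center.  A common window length (the rounded
#' mean of the two protected lengths) is used at both positions, so the
#' delta is exactly 0 when the centers coincide and antisymmetric under
#' swapping the time points.
#'
#' @param pairs A [pair_calls()] result.
#' @param track Preference track (`annotation_track`).
#' @return A data.frame: `score_t0`, `score_t3`, `delta_predicted`
#'   (`NA` where a footprint is unevaluable).
#' @export
delta_predicted <- function(pairs, track) {
  wlen <- as.integer(round((pairs$protected_length_t0 +
                              pairs$protected_length_t3) / 2))
  s0 <- window_mean(track, pairs$chrom, pairs$center_t0, wlen)
  s3 <- window_mean(track, pairs$chrom, pairs$center_t3, wlen)
  d <- s3 - s0
  d[pairs$center_t0 == pairs$center_t3] <- 0
  data.frame(score_t0 = s0, score_t3 = s3, delta_predicted = d)
}

#' Correlate predicted-occupancy changes with observed occupancy changes
#'
#' Pearson correlation between the per-pair change in footprint-mean
#' preference score ([delta_predicted()]) and the observed log2
#' occupancy change, plus, per classification class, the mean score at
#' the 0 h and 3 h positions with a paired t-test p-value.
#'
#' @param pairs A [pair_calls()] result (typically restricted to pairs
#'   with any position shift).
#' @param delta_log2_observed Observed log2 occupancy changes, one per
#'   pair (e.g. `log2(k3 / k0)`).
#' @param track Preference track.
#' @param classes Optional character vector of class labels per pair.
#' @return A list: `r` (`NA` with `degenerate = TRUE` when the predicted
#'   deltas have no variance), `n`, `per_pair` data.frame, and
#'   `class_summary` (per class: n, mean score at t0/t3, paired p).
#' @export
delta_correlation <- function(pairs, delta_log2_observed, track,
                              classes = NULL) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  dp <- delta_predicted(pairs, track)
  ok <- is.finite(dp$delta_predicted) & is.finite(delta_log2_observed)
  degenerate <- sum(ok) < 3L || sd(dp$delta_predicted[ok]) == 0 ||
    sd(delta_log2_observed[ok]) == 0
  r <- if (degenerate) NA_real_ else
    cor(dp$delta_predicted[ok], delta_log2_observed[ok])

  class_summary <- NULL
  if (!is.null(classes)) {
    rows <- lapply(unique(classes), function(cl) {
      sel <- which(classes == cl & is.finite(dp$score_t0) &
                     is.finite(dp$score_t3))
      p <- if (length(sel) >= 2L &&
               sd(dp$score_t3[sel] - dp$score_t0[sel]) > 0) {
        t.test(dp$score_t3[sel], dp$score_t0[sel], paired = TRUE)$p.value
      } else NA_real_
      data.frame(class = cl, n = length(sel),
                 mean_score_t0 = mean(dp$score_t0[sel]),
                 mean_score_t3 = mean(dp$score_t3[sel]),
                 paired_p = p, stringsAsFactors = FALSE)
    })
    class_summary <- do.call(rbind, rows)
  }
  list(r = r, n = sum(ok), degenerate = degenerate,
       per_pair = cbind(dp, delta_log2_observed = delta_log2_observed),
       class_summary = class_summary)
}
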