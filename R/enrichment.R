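#' Score nucleosomes against an annotation track
#'
#' The score of a nucleosome is the mean track value over its protected
#' footprint (`center +/- protected_length / 2`), ignoring missing bases;
#' a footprint with no data at all scores `NA` ("absent").  Averaging
#' over the footprint makes scores comparable across platforms of
#' different resolution.
#'
#' @param track An `annotation_track` or `density_track` (per-base
#'   values, `NA` = missing).
#' @param calls A `nucleosome_calls` (or compatible) data.frame.
#' @return Numeric vector of per-nucleosome scores.
#' @export
score_nucleosomes <- function(track, calls) {
  out <- rep(NA_real_, nrow(calls))
  for (cc in unique(calls$chrom)) {
    v <- track$values[[cc]]
    if (is.null(v)) next
    n <- length(v)
    cs_val <- cumsum(c(0, ifelse(is.na(v), 0, v)))
    cs_n <- cumsum(c(0, !is.na(v)))
    sel <- which(calls$chrom == cc)
    half <- calls$protected_length[sel] %/% 2L
    lo <- pmax(calls$center[sel] - half, 0L)
    hi <- pmin(calls$center[sel] + half, n - 1L)
    cnt <- cs_n[hi + 2L] - cs_n[lo + 1L]
    tot <- cs_val[hi + 2L] - cs_val[lo + 1L]
    out[sel] <- ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  out
}

new_enrichment_result <- function(class_name, n_class, observed, rnd,
                                  n_random, seed) {
  rm <- mean(rnd)
  rs <- sd(rnd)
  degenerate <- !is.finite(rs) || rs == 0
  z <- if (degenerate) 0 else (observed - rm) / rs
  p <- 2 * pnorm(-abs(z))
  structure(list(class_name = class_name, n_class = n_class,
                 observed = observed, random_mean = rm, random_sd = rs,
                 z = z, p_value = p, neg_log10_p = -log10(p),
                 n_random = n_random, seed = seed, degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s (n=%d): observed %.4g, random %.4g +/- %.3g, z = %.3f, -log10 p = %.3f%s\n",
              x$class_name, x$n_class, x$observed, x$random_mean, x$random_sd,
              x$z, x$neg_log10_p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Permutation z-score enrichment of a nucleosome class
#'
#' The observed statistic is the mean annotation score of the class.  Its
#' null distribution is estimated by drawing, `n_random` times, an
#' identical number of nucleosomes from the universe without replacement
#' and recomputing the mean; the z-score is the observed mean's deviation
#' in units of the random s.d., and significance is reported as the
#' `-log10` of the two-sided normal tail p-value of z.
#'
#' @param universe_calls Calls data.frame: the universe the class is
#'   drawn from (e.g. all depletion-dependent nucleosomes).
#' @param class_idx Integer or logical index of the class within
#'   `universe_calls`.
#' @param track Annotation track (or a precomputed numeric score vector
#'   of length `nrow(universe_calls)`).
#' @param n_random Number of randomisations.
#' @param seed Integer seed (randomisations are seed-deterministic).
#' @param class_name Label carried into the result.
#' @return An `enrichment_result`.
#' @export
class_enrichment <- function(universe_calls, class_idx, track,
                             n_random = 100L, seed = 1L,
                             class_name = "class") {
  if (is.logical(class_idx)) class_idx <- which(class_idx)
  m <- length(class_idx)
  if (m < 1L) stop("empty class", call. = FALSE)
  if (m > nrow(universe_calls)) {
    stop("class larger than universe", call. = FALSE)
  }
  scores <- if (is.numeric(track)) track else
    score_nucleosomes(track, universe_calls)
  observed <- mean(scores[class_idx], na.rm = TRUE)
  withr::local_seed(seed)
  rnd <- vapply(seq_len(n_random), function(i) {
    mean(scores[sample.int(length(scores), m)], na.rm = TRUE)
  }, numeric(1))
  new_enrichment_result(class_name, m, observed, rnd, n_random, seed)
}

#' Split nucleosomes into genic and intergenic sets
#'
#' A nucleosome is genic iff its dyad lies inside a transcribed interval
#' (0-based, half-open: a dyad at `start` is genic, at `end` is not).
#'
#' @param calls Calls data.frame.
#' @param transcribed Data.frame of transcribed intervals (`chrom`,
#'   `start`, `end`).
#' @return Logical vector: `TRUE` = genic.
#' @export
split_genic <- function(calls, transcribed) {
  points_in_intervals(calls$chrom, calls$center, transcribed)
}

#' Region-overlap enrichment of a nucleosome class
#'
#' The observed statistic is the number of class nucleosomes whose
#' footprint intersects any region (e.g. promoters of genes with
#' increased expression); the null is built by repeatedly drawing an
#' identical number of nucleosomes from the universe, as in
#' [class_enrichment()].
#'
#' @inheritParams class_enrichment
#' @param regions Data.frame of regions (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return An `enrichment_result` (with `observed` a count).
#' @export
region_overlap_enrichment <- function(universe_calls, class_idx, regions,
                                      n_random = 100L, seed = 1L,
                                      class_name = "class") {
  if (is.logical(class_idx)) class_idx <- which(class_idx)
  m <- length(class_idx)
  if (m < 1L) stop("empty class", call. = FALSE)
  if (m > nrow(universe_calls)) stop("class larger than universe", call. = FALSE)
  hit <- logical(nrow(universe_calls))
  if (nrow(regions) > 0L) {
    fb <- footprint_bounds(universe_calls$center,
                           universe_calls$protected_length)
    for (cc in unique(universe_calls$chrom)) {
      iv <- regions[regions$chrom == cc, , drop = FALSE]
      if (nrow(iv) == 0L) next
      sel <- which(universe_calls$chrom == cc)
      q <- IRanges::IRanges(fb$start[sel] + 1L, fb$end[sel])
      s <- IRanges::IRanges(iv$start + 1L, iv$end)
      hit[sel] <- IRanges::overlapsAny(q, s)
    }
  }
  observed <- sum(hit[class_idx])
  withr::local_seed(seed)
  rnd <- vapply(seq_len(n_random), function(i) {
    sum(hit[sample.int(length(hit), m)])
  }, numeric(1))
  new_enrichment_result(class_name, m, observed, rnd, n_random, seed)
}

#' Cross-replicate shift-direction consistency
#'
#' For each consensus nucleosome, counts how many informative replicates
#' (those reporting a left or right shift) agree with the majority
#' direction.  Exact ties are flagged uninformative.
#'
#' @param consensus A [replicate_consensus()] result (the
#'   `rep_shift_direction` list-column is used).
#' @return A data.frame: `n_same_direction`, `n_informative`,
#'   `majority_direction` (`left` / `right`, `NA` on ties or no
#'   information).
#' @export
shift_direction_consistency <- function(consensus) {
  res <- t(vapply(consensus$rep_shift_direction, function(d) {
    d <- d[d %in% c("left", "right")]
    nl <- sum(d == "left"); nr <- sum(d == "right")
    if (nl + nr == 0L || nl == nr) return(c(NA_real_, nl + nr, NA_real_))
    c(max(nl, nr), nl + nr, if (nr > nl) 1 else -1)
  }, numeric(3)))
  data.frame(n_same_direction = as.integer(res[, 1L]),
             n_informative = as.integer(res[, 2L]),
             majority_direction = ifelse(is.na(res[, 3L]), NA_character_,
                                         ifelse(res[, 3L] > 0, "right", "left")),
             stringsAsFactors = FALSE)
}

#' Association between shift direction and nearby occupancy loss
#'
#' For each focal nucleosome with a consensus shift direction, asks
#' whether a consensus occupancy-reduced nucleosome exists within
#' `window` bp on the shift side: "toward loss" when yes and none lies on
#' the opposite side, "away" in the reverse configuration, uninformative
#' otherwise (including tied shift directions).  A two-sided binomial
#' test compares toward vs away counts against 1/2.
#'
#' @param shifted_consensus Consensus rows for the focal (shifted)
#'   nucleosomes.
#' @param classified_consensus Consensus rows for the full classified
#'   set (source of `reduced` nucleosomes).
#' @param window Scan distance (bp).
#' @return A list: `toward`, `away`, `uninformative`, `p_value` (`NA`
#'   and `degenerate = TRUE` when no informative focal nucleosome
#'   exists), and the per-nucleosome `detail` data.frame.
#' @export
directional_occupancy_association <- function(shifted_consensus,
                                              classified_consensus,
                                              window = 600L) {
  if (nrow(shifted_consensus) == 0L) {
    stop("empty shifted set", call. = FALSE)
  }
  dirs <- shift_direction_consistency(shifted_consensus)$majority_direction
  red <- classified_consensus[
    classified_consensus$consensus_occupancy == "reduced", , drop = FALSE]
  status <- character(nrow(shifted_consensus))
  for (i in seq_len(nrow(shifted_consensus))) {
    if (is.na(dirs[i])) { status[i] <- "uninformative"; next }
    d <- shifted_consensus$consensus_dyad[i]
    rr <- red[red$chrom == shifted_consensus$chrom[i], , drop = FALSE]
    delta <- rr$consensus_dyad - d
    sgn <- if (dirs[i] == "right") 1L else -1L
    on_side <- any(delta * sgn > 0 & abs(delta) <= window)
    on_opp <- any(delta * sgn < 0 & abs(delta) <= window)
    status[i] <- if (on_side && !on_opp) "toward" else
      if (on_opp && !on_side) "away" else "uninformative"
  }
  toward <- sum(status == "toward")
  away <- sum(status == "away")
  p <- if (toward + away > 0) {
    binom.test(toward, toward + away, 0.5)$p.value
  } else NA_real_
  list(toward = toward, away = away,
       uninformative = sum(status == "uninformative"),
       p_value = p, degenerate = toward + away == 0,
       detail = data.frame(chrom = shifted_consensus$chrom,
                           consensus_dyad = shifted_consensus$consensus_dyad,
                           direction = dirs, status = status,
                           stringsAsFactors = FALSE))
}

#' Linker distances around focal nucleosomes at both time points
#'
#' For each focal nucleosome, the gap (bp) between its footprint edge and
#' the nearest neighbouring call's footprint edge, upstream and
#' downstream, at 0 h and 3 h.  The focal call at each time point is the
#' call whose center is nearest the focal dyad (within `match_radius`);
#' chromosome-terminal sides and unmatched time points are `NA`.
#'
#' @param calls_t0,calls_t3 Calls data.frames (sorted by coordinate).
#' @param focal Data.frame with `chrom` and `dyad` of focal nucleosomes.
#' @param match_radius Maximum dyad-to-call distance (bp) for matching.
#' @return A data.frame: `up_t0`, `down_t0`, `up_t3`, `down_t3`.
#' @export
linker_distances <- function(calls_t0, calls_t3, focal, match_radius = 100L) {
  one_tp <- function(calls) {
    up <- rep(NA_real_, nrow(focal)); down <- rep(NA_real_, nrow(focal))
    for (cc in unique(focal$chrom)) {
      cl <- calls[calls$chrom == cc, , drop = FALSE]
      cl <- cl[order(cl$center), , drop = FALSE]
      if (nrow(cl) == 0L) next
      fb <- footprint_bounds(cl$center, cl$protected_length)
      sel <- which(focal$chrom == cc)
      for (i in sel) {
        j <- which.min(abs(cl$center - focal$dyad[i]))
        if (abs(cl$center[j] - focal$dyad[i]) > match_radius) next
        if (j > 1L) up[i] <- fb$start[j] - fb$end[j - 1L]
        if (j < nrow(cl)) down[i] <- fb$start[j + 1L] - fb$end[j]
      }
    }
    list(up = up, down = down)
  }
  a <- one_tp(calls_t0)
  b <- one_tp(calls_t3)
  data.frame(up_t0 = a$up, down_t0 = a$down, up_t3 = b$up, down_t3 = b$down)
}
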