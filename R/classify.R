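#' Classification thresholds
#'
#' The decision regions for position and occupancy verdicts.  Position:
#' `altered` when the Bonferroni-corrected t-test p-value is below
#' `pos_altered`, `unchanged` when above `pos_unchanged`, otherwise
#' `no_call`.  Occupancy (binomial test on windowed read-center counts):
#' `reduced` when the corrected lower-tail p is below `occ_reduced`,
#' `retained` when the corrected upper-tail p is below `occ_retained`
#' (the corrected-tail rendering of "p > 0.99"), `unchanged` when the raw
#' lower-tail p lies strictly inside `occ_unchanged`, otherwise
#' `no_call`.  Pairing requires footprints to overlap by at least
#' `overlap_min` bp and both occupancies to exceed `coverage_min` reads.
#'
#' @param pos_altered,pos_unchanged Position thresholds (corrected p).
#' @param occ_reduced,occ_retained Occupancy tail thresholds (corrected).
#' @param occ_unchanged Raw lower-tail p interval (open) for `unchanged`.
#' @param overlap_min Minimum footprint overlap (bp) for pairing.
#' @param coverage_min Occupancy must exceed this count on both sides.
#' @param occ_window Occupancy counting window (bp, centered on the
#'   anchor dyad).
#' @return A `classification_thresholds` list.
#' @export
classification_thresholds <- function(pos_altered = 0.01, pos_unchanged = 0.2,
                                      occ_reduced = 0.01, occ_retained = 0.01,
                                      occ_unchanged = c(0.2, 0.8),
                                      overlap_min = 30L, coverage_min = 5L,
                                      occ_window = 100L) {
  structure(list(pos_altered = pos_altered, pos_unchanged = pos_unchanged,
                 occ_reduced = occ_reduced, occ_retained = occ_retained,
                 occ_unchanged = occ_unchanged,
                 overlap_min = as.integer(overlap_min),
                 coverage_min = as.integer(coverage_min),
                 occ_window = as.integer(occ_window)),
            class = "classification_thresholds")
}

#' Pair 0 h and 3 h nucleosome calls
#'
#' Candidate pairs are calls whose half-open footprints overlap by at
#' least `overlap_min` bp; calls failing the coverage filter
#' (`occupancy <= coverage_min`) are removed before matching.  Each call
#' participates in at most one pair: candidates are taken greedily by
#' descending overlap, ties by leftmost 0 h center.  The pair's consensus
#' dyad is the rounded mean of the two centers.
#'
#' @param calls_t0,calls_t3 `nucleosome_calls` data.frames.
#' @param thresholds A [classification_thresholds()] object.
#' @return A data.frame of pairs (indices into the input call tables,
#'   centers, overlap, consensus dyad, occupancies and member summary
#'   statistics from both sides), with attributes `unpaired_t0` and
#'   `unpaired_t3` (indices of coverage-passing calls left unpaired).
#' @export
pair_calls <- function(calls_t0, calls_t3,
                       thresholds = classification_thresholds()) {
  th <- thresholds
  keep0 <- which(calls_t0$occupancy > th$coverage_min)
  keep3 <- which(calls_t3$occupancy > th$coverage_min)
  c0 <- calls_t0[keep0, , drop = FALSE]
  c3 <- calls_t3[keep3, , drop = FALSE]

  cand <- NULL
  if (nrow(c0) && nrow(c3)) {
    fb0 <- footprint_bounds(c0$center, c0$protected_length)
    fb3 <- footprint_bounds(c3$center, c3$protected_length)
    pieces <- list()
    for (cc in intersect(unique(c0$chrom), unique(c3$chrom))) {
      i0 <- which(c0$chrom == cc)
      i3 <- which(c3$chrom == cc)
      q <- IRanges::IRanges(fb0$start[i0] + 1L, fb0$end[i0])
      s <- IRanges::IRanges(fb3$start[i3] + 1L, fb3$end[i3])
      hits <- IRanges::findOverlaps(q, s, minoverlap = th$overlap_min)
      if (length(hits) == 0L) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      pieces[[cc]] <- data.frame(i0 = i0[qh], i3 = i3[sh], overlap = ov)
    }
    if (length(pieces)) cand <- do.call(rbind, pieces)
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    out <- data.frame(idx_t0 = integer(), idx_t3 = integer(),
                      chrom = character(), center_t0 = integer(),
                      center_t3 = integer(), overlap_bp = integer(),
                      consensus_dyad = integer(), occupancy_t0 = integer(),
                      occupancy_t3 = integer(), stringsAsFactors = FALSE)
    attr(out, "unpaired_t0") <- keep0
    attr(out, "unpaired_t3") <- keep3
    return(out)
  }

  ord <- order(-cand$overlap, c0$center[cand$i0], c3$center[cand$i3])
  cand <- cand[ord, , drop = FALSE]
  i0v <- cand$i0; i3v <- cand$i3
  used0 <- logical(nrow(c0)); used3 <- logical(nrow(c3))
  take <- logical(nrow(cand))
  for (k in seq_along(i0v)) {
    a <- i0v[k]; b <- i3v[k]
    if (!used0[a] && !used3[b]) {
      used0[a] <- TRUE; used3[b] <- TRUE; take[k] <- TRUE
    }
  }
  cand <- cand[take, , drop = FALSE]

  out <- data.frame(
    idx_t0 = keep0[cand$i0], idx_t3 = keep3[cand$i3],
    chrom = c0$chrom[cand$i0],
    center_t0 = c0$center[cand$i0], center_t3 = c3$center[cand$i3],
    overlap_bp = cand$overlap,
    consensus_dyad = as.integer(round((c0$center[cand$i0] +
                                         c3$center[cand$i3]) / 2)),
    occupancy_t0 = c0$occupancy[cand$i0], occupancy_t3 = c3$occupancy[cand$i3],
    n_members_t0 = c0$n_members[cand$i0], n_members_t3 = c3$n_members[cand$i3],
    member_mean_t0 = c0$member_mean[cand$i0],
    member_mean_t3 = c3$member_mean[cand$i3],
    member_var_t0 = c0$member_var[cand$i0],
    member_var_t3 = c3$member_var[cand$i3],
    protected_length_t0 = c0$protected_length[cand$i0],
    protected_length_t3 = c3$protected_length[cand$i3],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$center_t0), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired_t0") <- setdiff(keep0, out$idx_t0)
  attr(out, "unpaired_t3") <- setdiff(keep3, out$idx_t3)
  out
}

# vectorised Welch t-test from summary statistics; returns raw p-values
welch_p <- function(n0, m0, v0, n1, m1, v1) {
  se2 <- v0 / n0 + v1 / n1
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(tt)] <- NA_real_
  p
}

#' Classify the position change of paired nucleosomes
#'
#' Welch (unequal-variance) two-sample t-test comparing the member
#' read-center distributions of the 0 h and 3 h calls, Bonferroni
#' corrected by `n_tests`.  Pairs with fewer than 2 members on either
#' side or zero pooled variance are degenerate `no_call`s.
#'
#' @param pairs A [pair_calls()] result.
#' @param n_tests Bonferroni correction factor: the number of nucleosome
#'   pairs compared in this replicate (default `nrow(pairs)`).
#' @param thresholds A [classification_thresholds()] object.
#' @return A data.frame: `position_p_raw`, `position_p_corrected`,
#'   `position_call` (`altered` / `unchanged` / `no_call`), `shift_bp`
#'   (signed `center_t3 - center_t0`), `shift_direction`
#'   (`left` / `right` / `none`), `position_degenerate`.
#' @export
classify_position <- function(pairs, n_tests = nrow(pairs),
                              thresholds = classification_thresholds()) {
  th <- thresholds
  n0 <- pairs$n_members_t0; n1 <- pairs$n_members_t3
  degen <- n0 < 2L | n1 < 2L |
    (pairs$member_var_t0 + pairs$member_var_t3) <= 0
  p <- rep(NA_real_, nrow(pairs))
  ok <- !degen
  p[ok] <- welch_p(n0[ok], pairs$member_mean_t0[ok], pairs$member_var_t0[ok],
                   n1[ok], pairs$member_mean_t3[ok], pairs$member_var_t3[ok])
  degen <- degen | is.na(p)
  pc <- pmin(1, p * n_tests)
  call <- rep("no_call", nrow(pairs))
  call[!degen & pc < th$pos_altered] <- "altered"
  call[!degen & pc > th$pos_unchanged] <- "unchanged"
  shift <- pairs$center_t3 - pairs$center_t0
  dir <- ifelse(shift > 0L, "right", ifelse(shift < 0L, "left", "none"))
  data.frame(position_p_raw = p, position_p_corrected = pc,
             position_call = call, shift_bp = shift, shift_direction = dir,
             position_degenerate = degen, stringsAsFactors = FALSE)
}

#' Classify the occupancy change of paired nucleosomes
#'
#' Binomial test on the read-center counts `k0` (0 h) and `k3` (3 h) in
#' the occupancy window: under no change, `k3 ~ Binomial(k0 + k3, 1/2)`.
#' The lower tail `P(X <= k3)` supports `reduced`, the upper tail
#' `P(X >= k3)` supports `retained`; both are Bonferroni corrected by
#' `n_tests`, while the `unchanged` band is applied to the raw lower-tail
#' p-value.
#'
#' @param k0,k3 Non-negative integer counts (depth-normalised).
#' @param n_tests Bonferroni correction factor.
#' @param thresholds A [classification_thresholds()] object.
#' @return A data.frame: `occ_p_lower`, `occ_p_upper` (raw tails),
#'   `occ_p_lower_corrected`, `occ_p_upper_corrected`, `occupancy_call`
#'   (`reduced` / `unchanged` / `retained` / `no_call`).
#' @export
classify_occupancy <- function(k0, k3, n_tests = length(k0),
                               thresholds = classification_thresholds()) {
  if (any(k0 < 0 | k3 < 0)) stop("negative counts", call. = FALSE)
  th <- thresholds
  n <- k0 + k3
  pl <- pbinom(k3, n, 0.5)
  pu <- pbinom(k3 - 1, n, 0.5, lower.tail = FALSE)
  plc <- pmin(1, pl * n_tests)
  puc <- pmin(1, pu * n_tests)
  call <- rep("no_call", length(k0))
  red <- plc < th$occ_reduced
  ret <- puc < th$occ_retained
  unch <- !red & !ret & pl > th$occ_unchanged[1L] & pl < th$occ_unchanged[2L]
  call[red] <- "reduced"
  call[ret] <- "retained"
  call[unch] <- "unchanged"
  call[n == 0] <- "no_call"
  data.frame(occ_p_lower = pl, occ_p_upper = pu,
             occ_p_lower_corrected = plc, occ_p_upper_corrected = puc,
             occupancy_call = call, stringsAsFactors = FALSE)
}

# count sorted centers within [lo, hi] (inclusive, 0-based)
count_in_window <- function(sorted_centers, lo, hi) {
  findInterval(hi, sorted_centers) - findInterval(lo - 1L, sorted_centers)
}

#' Classify all pairs of one replicate
#'
#' Runs position and occupancy classification for every pair.  Occupancy
#' counts are read centers within half the occupancy window of the
#' anchor: the pair's consensus dyad (`anchor = "consensus"`, the
#' default) or each call's own center (`anchor = "respective"`).  Both
#' time points' center lists should be depth-normalised (see
#' [subsample_centers()]) before counting.
#'
#' @param pairs A [pair_calls()] result.
#' @param centers_t0,centers_t3 [center_list()] objects for the two time
#'   points; when `NULL`, the calls' own `occupancy` fields are used as
#'   counts (equivalent to `anchor = "respective"`).
#' @param n_tests Bonferroni factor (default: number of pairs).
#' @param thresholds A [classification_thresholds()] object.
#' @param anchor Occupancy window anchor.
#' @return The pairs data.frame augmented with all classification
#'   columns plus `k0` and `k3`.
#' @export
classify_pairs <- function(pairs, centers_t0 = NULL, centers_t3 = NULL,
                           n_tests = nrow(pairs),
                           thresholds = classification_thresholds(),
                           anchor = c("consensus", "respective")) {
  anchor <- match.arg(anchor)
  th <- thresholds
  hw <- th$occ_window %/% 2L
  if (is.null(centers_t0) || is.null(centers_t3)) {
    k0 <- pairs$occupancy_t0
    k3 <- pairs$occupancy_t3
  } else {
    a0 <- if (anchor == "consensus") pairs$consensus_dyad else pairs$center_t0
    a3 <- if (anchor == "consensus") pairs$consensus_dyad else pairs$center_t3
    k0 <- integer(nrow(pairs)); k3 <- integer(nrow(pairs))
    for (cc in unique(pairs$chrom)) {
      sel <- pairs$chrom == cc
      k0[sel] <- count_in_window(centers_t0$centers[[cc]], a0[sel] - hw,
                                 a0[sel] + hw)
      k3[sel] <- count_in_window(centers_t3$centers[[cc]], a3[sel] - hw,
                                 a3[sel] + hw)
    }
  }
  pos <- classify_position(pairs, n_tests, th)
  occ <- classify_occupancy(k0, k3, n_tests, th)
  cbind(pairs, data.frame(k0 = k0, k3 = k3), pos, occ)
}

#' Link per-replicate classifications and form the consensus
#'
#' Classified nucleosomes are linked across replicates by greedy
#' nearest-dyad matching: clusters are seeded from the first replicate
#' and each subsequent replicate's nucleosomes join the nearest cluster
#' whose running mean dyad lies within `link_radius` bp (74 bp, half a
#' canonical footprint), else seed a new cluster; a cluster accepts at
#' most one nucleosome per replicate.  A consensus label requires at
#' least two replicates with the identical informative label and no
#' competing label with equal support; the occupancy consensus is
#' additionally vetoed when any two replicates are oppositely classified
#' (`reduced` vs `retained`).  Position and occupancy consensus are
#' computed independently.
#'
#' @param replicates List (length >= 2) of [classify_pairs()] results.
#' @param link_radius Linking radius in bp.
#' @return A data.frame of consensus nucleosomes: `chrom`,
#'   `consensus_dyad` (rounded mean of supporting replicates' 0 h
#'   centers), `support` (replicates linked), per-label support counts,
#'   `consensus_position`, `consensus_occupancy`, and list-columns
#'   `rep_position`, `rep_occupancy`, `rep_shift_bp`,
#'   `rep_shift_direction` with the per-replicate values.
#' @export
replicate_consensus <- function(replicates, link_radius = 74L) {
  if (length(replicates) < 2L) {
    stop("consensus requires at least two replicates", call. = FALSE)
  }
  # cluster assembly per chromosome (greedy linking in compiled code)
  chroms <- sort(unique(unlist(lapply(replicates,
                                      function(r) unique(r$chrom)))))
  chrom_v <- character(0); rep_v <- integer(0); row_v <- integer(0)
  cid_v <- integer(0)
  cid_offset <- 0L
  for (cc in chroms) {
    rows_by_rep <- lapply(replicates, function(r) {
      rows <- which(r$chrom == cc)
      rows[order(r$center_t0[rows])]
    })
    sizes <- lengths(rows_by_rep)
    if (sum(sizes) == 0L) next
    ctrs <- unlist(lapply(seq_along(replicates), function(ri) {
      replicates[[ri]]$center_t0[rows_by_rep[[ri]]]
    }), use.names = FALSE)
    cid <- link_clusters_chrom(as.numeric(ctrs), as.integer(sizes),
                               as.numeric(link_radius))
    chrom_v <- c(chrom_v, rep(cc, sum(sizes)))
    rep_v <- c(rep_v, rep(seq_along(replicates), sizes))
    row_v <- c(row_v, unlist(rows_by_rep, use.names = FALSE))
    cid_v <- c(cid_v, cid + cid_offset)
    cid_offset <- cid_offset + max(cid)
  }
  if (!length(cid_v)) {
    return(data.frame(chrom = character(), consensus_dyad = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  }

  pick <- function(col) {
    out <- replicates[[1L]][[col]][rep(NA_integer_, length(rep_v))]
    for (ri in seq_along(replicates)) {
      sel <- rep_v == ri
      out[sel] <- replicates[[ri]][[col]][row_v[sel]]
    }
    out
  }
  pos_labs <- pick("position_call")
  occ_labs <- pick("occupancy_call")
  shifts <- pick("shift_bp")
  dirs <- pick("shift_direction")
  t0c <- pick("center_t0")

  support <- tabulate(cid_v)
  cnt <- function(v, lab) {
    tabulate(cid_v[!is.na(v) & v == lab], nbins = length(support))
  }
  n_altered <- cnt(pos_labs, "altered")
  n_pos_unchanged <- cnt(pos_labs, "unchanged")
  n_reduced <- cnt(occ_labs, "reduced")
  n_occ_unchanged <- cnt(occ_labs, "unchanged")
  n_retained <- cnt(occ_labs, "retained")

  # consensus label: >=2 identical informative labels and no competing
  # label with support >=2; occupancy additionally vetoed when opposite
  # classifications coexist
  pick_label <- function(counts, labels) {
    m <- do.call(cbind, counts)
    hit <- m >= 2L
    n_hit <- rowSums(hit)
    out <- rep("none", nrow(m))
    one <- n_hit == 1L
    out[one] <- labels[max.col(hit[one, , drop = FALSE], "first")]
    out
  }
  consensus_position <- pick_label(list(n_altered, n_pos_unchanged),
                                   c("altered", "unchanged"))
  consensus_occupancy <- pick_label(
    list(n_reduced, n_occ_unchanged, n_retained),
    c("reduced", "unchanged", "retained"))
  veto <- n_reduced >= 1L & n_retained >= 1L
  consensus_occupancy[veto] <- "none"

  cf <- factor(cid_v, levels = seq_along(support))
  dyad <- as.integer(round(rowsum(as.numeric(t0c), cf)[, 1L] / support))
  chrom_per_cluster <- chrom_v[!duplicated(cid_v)][order(unique(cid_v))]

  out <- data.frame(
    chrom = chrom_per_cluster,
    consensus_dyad = dyad,
    support = support,
    n_altered = n_altered,
    n_pos_unchanged = n_pos_unchanged,
    n_reduced = n_reduced,
    n_occ_unchanged = n_occ_unchanged,
    n_retained = n_retained,
    consensus_position = consensus_position,
    consensus_occupancy = consensus_occupancy,
    stringsAsFactors = FALSE
  )
  out$rep_position <- I(unname(split(pos_labs, cf)))
  out$rep_occupancy <- I(unname(split(occ_labs, cf)))
  out$rep_shift_bp <- I(unname(split(shifts, cf)))
  out$rep_shift_direction <- I(unname(split(dirs, cf)))
  out <- out[order(out$chrom, out$consensus_dyad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isolate depletion-dependent consensus nucleosomes
#'
#' A shutoff-strain consensus nucleosome is removed from the
#' depletion-dependent set (independently per attribute) when a
#' wildtype-strain consensus nucleosome within `link_radius` bp carries
#' the identical consensus label: such behaviour is attributable to the
#' carbon-source switch rather than to histone depletion.
#'
#' @param shutoff_consensus,wildtype_consensus [replicate_consensus()]
#'   results for the two strains (same genome layout).
#' @param link_radius Matching radius in bp.
#' @return `shutoff_consensus` augmented with logical columns
#'   `position_depletion_dependent` and `occupancy_depletion_dependent`,
#'   plus an attribute `label_counts`: per label, the number of
#'   consensus nucleosomes classified in the shutoff strain only, the
#'   wildtype strain only, or identically in both.
#' @export
depletion_dependent <- function(shutoff_consensus, wildtype_consensus,
                                link_radius = 74L) {
  sc <- shutoff_consensus
  wc <- wildtype_consensus
  match_label <- function(attr_col) {
    matched <- logical(nrow(sc))
    wt_matched <- logical(nrow(wc))
    for (cc in unique(sc$chrom)) {
      si <- which(sc$chrom == cc & sc[[attr_col]] != "none")
      wi <- which(wc$chrom == cc & wc[[attr_col]] != "none")
      if (!length(si) || !length(wi)) next
      for (i in si) {
        hit <- wi[abs(wc$consensus_dyad[wi] - sc$consensus_dyad[i]) <=
                    link_radius & wc[[attr_col]][wi] == sc[[attr_col]][i]]
        if (length(hit)) {
          matched[i] <- TRUE
          wt_matched[hit] <- TRUE
        }
      }
    }
    list(shutoff = matched, wildtype = wt_matched)
  }
  mp <- match_label("consensus_position")
  mo <- match_label("consensus_occupancy")
  sc$position_depletion_dependent <- sc$consensus_position != "none" &
    !mp$shutoff
  sc$occupancy_depletion_dependent <- sc$consensus_occupancy != "none" &
    !mo$shutoff

  labs <- c(altered = "consensus_position", unchanged_position = "consensus_position",
            reduced = "consensus_occupancy", unchanged_occupancy = "consensus_occupancy",
            retained = "consensus_occupancy")
  lab_values <- c("altered", "unchanged", "reduced", "unchanged", "retained")
  counts <- data.frame(label = names(labs), shutoff_only = 0L,
                       wildtype_only = 0L, both = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    col <- labs[[i]]; lv <- lab_values[i]
    m <- if (col == "consensus_position") mp else mo
    s_has <- sc[[col]] == lv
    w_has <- wc[[col]] == lv
    counts$both[i] <- sum(s_has & m$shutoff)
    counts$shutoff_only[i] <- sum(s_has & !m$shutoff)
    counts$wildtype_only[i] <- sum(w_has & !m$wildtype)
  }
  attr(sc, "label_counts") <- counts
  sc
}
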