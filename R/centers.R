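#' Construct a center list
#'
#' A `center_list` holds, per chromosome, the sorted 0-based coordinates of
#' MNase read centers (dyad estimates).  Duplicates are allowed.
#'
#' @param centers Named list of integer vectors (one per chromosome).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param discarded Named integer vector of discard tallies (QC).
#' @return An object of class `center_list`.
#' @export
center_list <- function(centers, chrom_sizes,
                        discarded = c(span_filter = 0L, out_of_bounds = 0L)) {
  stopifnot(is.list(centers), !is.null(names(chrom_sizes)))
  centers <- lapply(centers, function(x) sort(as.integer(x)))
  structure(list(centers = centers, chrom_sizes = chrom_sizes,
                 discarded = discarded),
            class = "center_list")
}

#' @export
print.center_list <- function(x, ...) {
  n <- sum(vapply(x$centers, length, 0L))
  cat("<center_list> ", n, " centers on ", length(x$centers),
      " chromosome(s); discarded: ",
      paste(names(x$discarded), x$discarded, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Total number of centers
#' @param x A `center_list`.
#' @return Integer count.
#' @export
n_centers <- function(x) sum(vapply(x$centers, length, 0L))

#' Estimate the average fragment length from single-end reads
#'
#' Finds the offset `d` maximising the cross-correlation between the
#' density of Watson-strand 5' read starts and the density of
#' Crick-strand 5' read ends shifted by `-d`, scanned over the candidate
#' range.  Ties are broken toward the smaller offset.  This recovers the
#' average span between the two sequenced ends of the underlying
#' fragments.
#'
#' @param reads Fragment/read data.frame with `chrom`, `start`, `end`,
#'   `strand` columns (single-end; both strands must be represented).
#' @param range Integer vector of length 2, the search window in bp.
#' @return The estimated fragment length (bp).
#' @export
estimate_fragment_length <- function(reads, range = c(50L, 300L)) {
  if (!all(c("+", "-") %in% reads$strand)) {
    stop("both strands must be represented to estimate fragment length",
         call. = FALSE)
  }
  lags <- seq.int(range[1L], range[2L])
  score <- numeric(length(lags))
  for (cc in unique(reads$chrom)) {
    r <- reads[reads$chrom == cc, , drop = FALSE]
    wpos <- r$start[r$strand == "+"]        # Watson 5' start
    cpos <- r$end[r$strand == "-"]          # Crick 5' end (half-open)
    if (!length(wpos) || !length(cpos)) next
    n <- max(wpos, cpos) + 1L
    w <- tabulate(wpos + 1L, nbins = n)
    cr <- tabulate(cpos + 1L, nbins = n)
    for (i in seq_along(lags)) {
      d <- lags[i]
      if (d < n) {
        score[i] <- score[i] +
          sum(w[seq_len(n - d)] * cr[seq.int(d + 1L, n)])
      }
    }
  }
  if (all(score == 0)) {
    stop("no cross-strand signal in the search range", call. = FALSE)
  }
  lags[which.max(score)]
}

#' Convert reads or fragments to read centers
#'
#' In paired mode, fragments with span outside 100-200 bp are discarded
#' (the pairing filter) and the center is `start + floor(span / 2)`.  In
#' single mode each read is extended to `fragment_length` from its 5' end
#' and the center is `start + floor(L / 2)` on `+`, `end - 1 -
#' floor(L / 2)` on `-`.  Centers falling outside the chromosome are
#' dropped.  All discards are tallied, never silent.
#'
#' @param reads Data.frame with `chrom`, `start`, `end` (and `strand` for
#'   single mode).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param mode `"paired"` or `"single"`.
#' @param fragment_length Required in single mode: the extension length.
#' @param span_range Pairing filter bounds (bp), inclusive.
#' @return A [center_list()].
#' @export
reads_to_centers <- function(reads, chrom_sizes, mode = c("paired", "single"),
                             fragment_length = NULL,
                             span_range = c(100L, 200L)) {
  mode <- match.arg(mode)
  chrom <- reads$chrom
  if (mode == "paired") {
    span <- reads$end - reads$start
    ok <- span >= span_range[1L] & span <= span_range[2L]
    n_span <- sum(!ok)
    ctr <- reads$start[ok] + span[ok] %/% 2L
    chrom <- chrom[ok]
  } else {
    if (is.null(fragment_length)) {
      stop("single mode requires `fragment_length`", call. = FALSE)
    }
    n_span <- 0L
    half <- as.integer(fragment_length) %/% 2L
    ctr <- ifelse(reads$strand == "+", reads$start + half,
                  reads$end - 1L - half)
  }
  clen <- unname(chrom_sizes[chrom])
  inb <- !is.na(clen) & ctr >= 0L & ctr < clen
  n_oob <- sum(!inb)
  ctr <- as.integer(ctr[inb]); chrom <- chrom[inb]
  centers <- split(ctr, factor(chrom, levels = names(chrom_sizes)))
  center_list(centers, chrom_sizes,
              discarded = c(span_filter = n_span, out_of_bounds = n_oob))
}

#' Extend single-end reads to full fragment intervals
#'
#' Each read is extended to `fragment_length` bp from its 5' end (the
#' convention used when computing protected lengths from single-end data).
#'
#' @inheritParams reads_to_centers
#' @return A data.frame of extended intervals (`chrom`, `start`, `end`).
#' @export
extend_reads <- function(reads, chrom_sizes, fragment_length) {
  L <- as.integer(fragment_length)
  start <- ifelse(reads$strand == "+", reads$start, reads$end - L)
  end <- start + L
  clen <- unname(chrom_sizes[reads$chrom])
  start <- pmax(start, 0L)
  end <- pmin(end, clen)
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Remove centers falling inside excluded intervals
#'
#' Intervals are 0-based, half-open (a center equal to an interval's `end`
#' is kept).  Used e.g. to drop reads from the repetitive rDNA locus.
#'
#' @param centers A [center_list()].
#' @param excluded Data.frame with `chrom`, `start`, `end`.
#' @return A filtered `center_list`; the number removed is added to the
#'   discard tally.
#' @export
filter_excluded <- function(centers, excluded) {
  if (is.null(excluded) || nrow(excluded) == 0L) return(centers)
  removed <- 0L
  for (cc in names(centers$centers)) {
    iv <- excluded[excluded$chrom == cc, , drop = FALSE]
    if (nrow(iv) == 0L) next
    x <- centers$centers[[cc]]
    drop <- points_in_intervals(rep(cc, length(x)), x, iv)
    removed <- removed + sum(drop)
    centers$centers[[cc]] <- x[!drop]
  }
  centers$discarded <- c(centers$discarded, excluded_region = removed)
  centers
}

#' Subsample centers to a fixed sequencing depth
#'
#' Uniform sampling without replacement across the whole genome, used to
#' normalise libraries to a common depth (the study convention is 5
#' million read centers per sample) before occupancy comparisons.
#'
#' @param centers A [center_list()].
#' @param n Number of centers to retain (default 5e6).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `center_list` with exactly `n` centers.
#' @export
subsample_centers <- function(centers, n = 5e6, seed = 1L) {
  total <- n_centers(centers)
  n <- as.integer(n)
  if (n > total) {
    stop("requested ", n, " centers but only ", total, " available",
         call. = FALSE)
  }
  if (n == total) return(centers)
  withr::local_seed(seed)
  sizes <- vapply(centers$centers, length, 0L)
  pick <- sort(sample.int(total, n))
  offs <- cumsum(c(0L, sizes))
  for (i in seq_along(centers$centers)) {
    sel <- pick[pick > offs[i] & pick <= offs[i + 1L]] - offs[i]
    centers$centers[[i]] <- centers$centers[[i]][sel]
  }
  centers
}
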