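#' Discrete Gaussian smoothing kernel
#'
#' Evaluated at integer offsets over `[-window * sd, window * sd]` and
#' renormalised to unit mass, so convolution conserves the number of
#' contributing read centers away from chromosome ends.
#'
#' @param sd Kernel standard deviation (bp).
#' @param window Truncation half-width in multiples of `sd`.
#' @return Numeric vector of kernel weights summing to 1.
#' @export
gaussian_kernel <- function(sd = 10, window = 3) {
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  h <- floor(window * sd)
  k <- dnorm(seq.int(-h, h), mean = 0, sd = sd)
  k / sum(k)
}

#' Per-base read-center density
#'
#' @param centers A [center_list()].
#' @return A `density_track`: per-chromosome vectors of per-base center
#'   counts (`smoothing_sd = 0`).
#' @export
center_density <- function(centers) {
  vals <- lapply(names(centers$chrom_sizes), function(cc) {
    n <- centers$chrom_sizes[[cc]]
    x <- centers$centers[[cc]]
    if (is.null(x)) x <- integer()
    as.numeric(tabulate(x + 1L, nbins = n))
  })
  names(vals) <- names(centers$chrom_sizes)
  structure(list(values = vals, smoothing_sd = 0, kernel_window = NA_real_),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  cat("<density_track> ", length(x$values), " chromosome(s), total mass ",
      format(sum(vapply(x$values, sum, 0))), ", smoothing_sd = ",
      x$smoothing_sd, "\n", sep = "")
  invisible(x)
}

smooth_vector <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1L) %/% 2L
  if (n == 0L) return(x)
  y <- convolve(x, rev(kernel), type = "open")
  y[seq.int(h + 1L, h + n)]
}

#' Gaussian-smooth a density track
#'
#' Convolves each chromosome's per-base counts with a unit-mass discrete
#' Gaussian kernel (default s.d. 10 bp, truncated at 3 s.d.), producing
#' the smoothed dyad-density track that drives nucleosome calling.
#' Chromosome ends are zero-padded, so total mass is conserved for
#' centers at least one kernel half-width from the ends.
#'
#' @param track A raw `density_track` from [center_density()].
#' @param sd Kernel standard deviation (bp).
#' @param window Truncation half-width in multiples of `sd`.
#' @return A smoothed `density_track`.
#' @export
smooth_track <- function(track, sd = 10, window = 3) {
  k <- gaussian_kernel(sd, window)
  track$values <- lapply(track$values, smooth_vector, kernel = k)
  track$smoothing_sd <- sd
  track$kernel_window <- window
  track
}

#' Anchor-aligned profile matrix
#'
#' Extracts one row per anchor from a track, spanning `flank_up` bp
#' upstream to `flank_down` bp downstream of the anchor in transcription
#' orientation: minus-strand rows are reversed so downstream is always
#' rightward.  Out-of-bounds flanks are padded with `NA`.  This is the
#' machinery behind average dyad-density profiles aligned on +1
#' nucleosomes or TSSs.
#'
#' @param track A `density_track` (raw or smoothed).
#' @param anchors Data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param flank_up,flank_down Flank widths (bp).
#' @param sort_key Optional numeric vector (one per anchor) ordering the
#'   rows (e.g. gene length, shortest to longest).
#' @return A numeric matrix (anchors x positions) with an attribute
#'   `colmeans` holding the column mean profile (NA-aware); column names
#'   are signed offsets.
#' @export
aligned_profile <- function(track, anchors, flank_up = 200L,
                            flank_down = 800L, sort_key = NULL) {
  if (nrow(anchors) == 0L) stop("empty anchor list", call. = FALSE)
  offs <- seq.int(-flank_up, flank_down)
  m <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offs),
              dimnames = list(NULL, offs))
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) next
    pos <- anchors$pos[i]
    idx <- if (anchors$strand[i] == "-") pos - offs else pos + offs
    ok <- idx >= 0L & idx < length(v)
    m[i, ok] <- v[idx[ok] + 1L]
  }
  if (!is.null(sort_key)) m <- m[order(sort_key), , drop = FALSE]
  attr(m, "colmeans") <- colMeans(m, na.rm = TRUE)
  m
}
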