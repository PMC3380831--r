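#' Generate a synthetic annotation track with a known class effect
#'
#' Draws one score per planted nucleosome, `Normal(0, 1)` plus
#' `effect_size` for nucleosomes carrying `target_label`, and rasterises
#' the scores over each nucleosome's 0 h footprint at the stated platform
#' resolution (bin means replace per-base values for `resolution > 1`).
#' Bases outside any footprint are missing (`NA`), mirroring
#' interval-limited ChIP platforms.
#'
#' @param truth A [plant_truth()] result.
#' @param layout The matching layout.
#' @param target_label One of the labels present in `truth`.
#' @param effect_size Standardised mean shift added to the target class.
#' @param resolution Rasterisation bin width (bp).
#' @param seed Integer seed.
#' @param footprint Footprint length (bp) used for rasterisation.
#' @return A list with `track` (an `annotation_track`: per-chromosome
#'   per-base numeric vectors with `NA` for missing) and `scores` (the
#'   per-nucleosome draws, in `truth` row order).
#' @export
generate_annotation_track <- function(truth, layout, target_label,
                                      effect_size = 0, resolution = 1L,
                                      seed = 1L, footprint = 147L) {
  if (!target_label %in% truth$label) {
    stop("label `", target_label, "` not present in truth", call. = FALSE)
  }
  withr::local_seed(seed)
  scores <- rnorm(nrow(truth)) + effect_size * (truth$label == target_label)
  half <- footprint %/% 2L
  vals <- lapply(names(layout$chrom_sizes), function(cc) {
    n <- layout$chrom_sizes[[cc]]
    v <- rep(NA_real_, n)
    sel <- which(truth$chrom == cc)
    for (i in sel) {
      lo <- max(truth$dyad_t0[i] - half, 0L)
      hi <- min(truth$dyad_t0[i] + half, n - 1L)
      v[seq.int(lo + 1L, hi + 1L)] <- scores[i]
    }
    if (resolution > 1L) {
      nb <- ceiling(n / resolution)
      bin <- rep(seq_len(nb), each = resolution, length.out = n)
      bm <- tapply(v, bin, function(z) {
        if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
      })
      v <- as.numeric(bm)[bin]
    }
    v
  })
  names(vals) <- names(layout$chrom_sizes)
  track <- structure(list(values = vals, resolution = as.integer(resolution)),
                     class = "annotation_track")
  list(track = track, scores = scores)
}

#' Generate a DNA sequence-preference score track
#'
#' Produces a smooth standardised random field (Gaussian-smoothed white
#' noise, default 20 bp smoothing) standing in for a sequence-based
#' predicted-occupancy model score.  With `couple = TRUE` the planted
#' shifted nucleosomes are re-targeted at 3 h to the local score maximum
#' within `+/- shift_magnitude` of their 0 h dyad, and their 3 h
#' occupancy weight is modulated by the resulting change in footprint-mean
#' score (`2^(gain * standardised delta)` times lognormal noise), so that
#' observed occupancy changes and predicted-occupancy changes co-vary.
#'
#' @param layout A layout.
#' @param truth A [plant_truth()] result.
#' @param couple Logical; couple shifted dyads and occupancy to the track.
#' @param seed Integer seed.
#' @param smooth_sd Smoothing s.d. (bp) of the random field.
#' @param shift_magnitude Search half-width for coupled relocation (bp);
#'   defaults to the planted displacement observed in `truth`.
#' @param gain Occupancy-coupling strength (log2 units per s.d. of delta).
#' @param noise_sd Lognormal (log2) s.d. of incoherent occupancy noise
#'   applied to shifted nucleosomes when coupling.
#' @return A list with `track` (an `annotation_track`) and `truth` (the
#'   possibly modified truth).
#' @export
generate_preference_track <- function(layout, truth, couple = FALSE,
                                      seed = 1L, smooth_sd = 20,
                                      shift_magnitude = NULL, gain = 1,
                                      noise_sd = 0.3) {
  withr::local_seed(seed)
  k <- gaussian_kernel(smooth_sd, 3)
  vals <- lapply(names(layout$chrom_sizes), function(cc) {
    n <- layout$chrom_sizes[[cc]]
    smooth_vector(rnorm(n), k)
  })
  names(vals) <- names(layout$chrom_sizes)
  mu <- mean(unlist(vals, use.names = FALSE))
  sg <- sd(unlist(vals, use.names = FALSE))
  vals <- lapply(vals, function(v) (v - mu) / sg)
  track <- structure(list(values = vals, resolution = 1L),
                     class = "annotation_track")

  if (couple) {
    shf <- which(truth$label == "shifted")
    if (length(shf)) {
      sm <- shift_magnitude
      if (is.null(sm)) {
        sm <- max(abs(truth$dyad_t3[shf] - truth$dyad_t0[shf]))
      }
      half <- 73L
      delta <- numeric(length(shf))
      for (j in seq_along(shf)) {
        i <- shf[j]
        v <- vals[[truth$chrom[i]]]
        lo <- max(truth$dyad_t0[i] - sm, half)
        hi <- min(truth$dyad_t0[i] + sm, length(v) - half - 1L)
        win <- seq.int(lo, hi)
        d3 <- win[which.max(v[win + 1L])]
        truth$dyad_t3[i] <- d3
        s0 <- mean(v[seq.int(truth$dyad_t0[i] - half, truth$dyad_t0[i] + half) + 1L])
        s3 <- mean(v[seq.int(d3 - half, d3 + half) + 1L])
        delta[j] <- s3 - s0
      }
      sref <- sd(delta)
      if (is.na(sref) || sref == 0) sref <- 1
      truth$weight_t3[shf] <- truth$weight_t0[shf] *
        2^(gain * delta / sref + rnorm(length(shf), 0, noise_sd))
    }
  }
  list(track = track, truth = truth)
}

#' Assign expression classes to genes
#'
#' With probability `coupling`, a gene whose promoter contains a
#' reduced-labelled nucleosome dyad is classed `increased` (promoter
#' nucleosome loss de-represses the downstream gene); all remaining genes
#' draw their class from an independent categorical prior.
#'
#' @param layout A layout with genes and promoters.
#' @param truth A [plant_truth()] result.
#' @param coupling Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param prior Named prior probabilities for `increased`, `normal`,
#'   `decreased`.
#' @return Data.frame with `gene_id`, `chrom`, `class`.
#' @export
assign_expression_classes <- function(layout, truth, coupling = 0.8,
                                      seed = 1L,
                                      prior = c(increased = 0.40,
                                                normal = 0.45,
                                                decreased = 0.15)) {
  if (nrow(layout$genes) == 0L) stop("layout has no genes", call. = FALSE)
  withr::local_seed(seed)
  red <- truth[truth$label == "reduced", , drop = FALSE]
  prom <- layout$promoters
  has_red <- vapply(seq_len(nrow(prom)), function(i) {
    any(red$chrom == prom$chrom[i] &
          red$dyad_t0 >= prom$start[i] & red$dyad_t0 < prom$end[i])
  }, logical(1))
  has_red <- setNames(has_red, prom$gene_id)[layout$genes$gene_id]
  has_red[is.na(has_red)] <- FALSE

  cls <- sample(names(prior), nrow(layout$genes), replace = TRUE, prob = prior)
  coupled <- has_red & runif(nrow(layout$genes)) < coupling
  cls[coupled] <- "increased"
  data.frame(gene_id = layout$genes$gene_id, chrom = layout$genes$chrom,
             class = cls, stringsAsFactors = FALSE)
}
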