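#' Plant a nucleosome map and its depletion response
#'
#' Places dyads on a jittered grid with period `spacing_mean` along every
#' chromosome and assigns each nucleosome one of four behaviours for the
#' 0 h to 3 h perturbation: `reduced` (occupancy multiplied by
#' `reduce_factor`), `retained` (multiplied by `retain_factor`), `shifted`
#' (dyad displaced by exactly `shift_magnitude`), or `stable`.  When
#' `config$promoter_bias` is set, the reduced label is preferentially
#' assigned to promoter-overlapping dyads, emulating the promoter-biased
#' occupancy loss observed under histone depletion.
#'
#' @param layout A [generate_layout()] result.
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: a data.frame with columns
#'   `chrom`, `dyad_t0`, `dyad_t3`, `weight_t0`, `weight_t3`, `label`.
#' @export
plant_truth <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  if (config$spacing_mean < config$fragment_mean) {
    stop("spacing_mean must be >= fragment_mean so planted arrays are ",
         "resolvable", call. = FALSE)
  }
  withr::local_seed(config$seed + 1L)

  rows <- lapply(names(layout$chrom_sizes), function(cc) {
    len <- layout$chrom_sizes[[cc]]
    sp <- config$spacing_mean
    grid <- seq.int(sp %/% 2L, len - sp %/% 2L, by = sp)
    dy <- grid + sample.int(2L * config$jitter + 1L, length(grid),
                            replace = TRUE) - config$jitter - 1L
    dy <- pmin(pmax(dy, 74L), len - 75L)
    data.frame(chrom = cc, dyad_t0 = as.integer(dy), stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  n <- nrow(tr)

  tr$weight_t0 <- rlnorm(n, meanlog = 0, sdlog = 0.15)
  tr$label <- rep("stable", n)

  n_red <- round(config$reduce_fraction * n)
  n_ret <- round(config$retain_fraction * n)
  n_shf <- round(config$shift_fraction * n)
  if (n_red + n_ret + n_shf > n) stop("perturbation fractions exceed 1")

  avail <- seq_len(n)
  if (n_red > 0L) {
    w <- rep(1, length(avail))
    if (config$promoter_bias && nrow(layout$promoters) > 0L) {
      in_prom <- points_in_intervals(tr$chrom[avail], tr$dyad_t0[avail],
                                     layout$promoters)
      w[in_prom] <- 4
    }
    red <- sample(avail, n_red, prob = w)
    tr$label[red] <- "reduced"
    avail <- setdiff(avail, red)
  }
  if (n_ret > 0L) {
    ret <- sample(avail, n_ret)
    tr$label[ret] <- "retained"
    avail <- setdiff(avail, ret)
  }
  if (n_shf > 0L) {
    shf <- sample(avail, n_shf)
    tr$label[shf] <- "shifted"
  }

  tr$dyad_t3 <- tr$dyad_t0
  tr$weight_t3 <- tr$weight_t0
  is_red <- tr$label == "reduced"
  is_ret <- tr$label == "retained"
  is_shf <- tr$label == "shifted"
  tr$weight_t3[is_red] <- config$reduce_factor * tr$weight_t0[is_red]
  tr$weight_t3[is_ret] <- config$retain_factor * tr$weight_t0[is_ret]
  if (any(is_shf)) {
    sgn <- sample(c(-1L, 1L), sum(is_shf), replace = TRUE)
    d3 <- tr$dyad_t0[is_shf] + sgn * config$shift_magnitude
    # flip direction at chromosome edges so the displacement stays exact
    len <- layout$chrom_sizes[tr$chrom[is_shf]]
    oob <- d3 < 74L | d3 > len - 75L
    d3[oob] <- tr$dyad_t0[is_shf][oob] - sgn[oob] * config$shift_magnitude
    tr$dyad_t3[is_shf] <- as.integer(d3)
  }

  tr <- tr[, c("chrom", "dyad_t0", "dyad_t3", "weight_t0", "weight_t3",
               "label")]
  structure(tr, class = c("sim_truth", "data.frame"))
}

#' Build the remodeler-centering (gap-filling) scenario
#'
#' Constructs a genome of repeated eight-nucleosome units
#' `S S A F B D S S` at `spacing_mean` phasing.  At 3 h, `B` (the focal
#' nucleosome's neighbour on the shift side) is removed outright, `D` is
#' reduced to `reduced_weight` of its 0 h occupancy, and the focal
#' nucleosome `F` re-centers on the DNA freed between `A` and `D` (a
#' displacement of 82 bp for the default 165 bp spacing and 147 bp
#' footprint).  Half the units are mirrored so shifts occur in both
#' directions.  This is the geometry used to test the directional
#' shift-toward-loss association and linker equalisation.
#'
#' @param n_units Number of units (one focal nucleosome each).
#' @param config A [sim_config()] object (spacing, fuzziness, fragment and
#'   depth parameters are used).
#' @param reduced_weight 3 h occupancy multiplier for the `D` nucleosome.
#' @return A list with `layout`, `truth` (labels `stable`, `removed`,
#'   `reduced`, `shifted`) and `focal` (row indices of focal nucleosomes).
#' @export
simulate_isw2_truth <- function(n_units = 200L, config = sim_config(),
                                reduced_weight = 0.3) {
  withr::local_seed(config$seed + 2L)
  sp <- config$spacing_mean
  unit_len <- 8L * sp
  chrom_len <- as.integer(n_units * unit_len + 2L * sp)
  chroms <- "chr01"
  layout <- structure(list(
    chrom_sizes = setNames(chrom_len, chroms),
    genes = data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       tss = integer(), tts = integer(),
                       gene_id = character(), stringsAsFactors = FALSE),
    transcribed = data.frame(chrom = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE),
    promoters = data.frame(chrom = character(), start = integer(),
                           end = integer(), gene_id = character(),
                           stringsAsFactors = FALSE),
    excluded = data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  ), class = "genome_layout")

  # exact recentering displacement between the surviving flanks:
  # A at F - sp, D at F + 2*sp; footprint half-width 73/74 for 147 bp
  shift_bp <- as.integer(round((2L * sp - sp) / 2))  # 82 for sp = 165

  mirrored <- sample(c(FALSE, TRUE), n_units, replace = TRUE)
  rows <- vector("list", n_units)
  focal <- integer(n_units)
  lab_fwd <- c("stable", "stable", "stable", "shifted", "removed", "reduced",
               "stable", "stable")
  for (u in seq_len(n_units)) {
    base <- (u - 1L) * unit_len + sp
    off <- (0:7) * sp
    lab <- lab_fwd
    if (mirrored[u]) lab <- rev(lab)
    dy0 <- base + off
    dy3 <- dy0
    w0 <- rep(1, 8L)
    w3 <- w0
    f <- which(lab == "shifted")
    d3dir <- if (mirrored[u]) -shift_bp else shift_bp
    dy3[f] <- dy0[f] + d3dir
    w3[lab == "removed"] <- 0
    w3[lab == "reduced"] <- reduced_weight
    rows[[u]] <- data.frame(chrom = chroms, dyad_t0 = as.integer(dy0),
                            dyad_t3 = as.integer(dy3), weight_t0 = w0,
                            weight_t3 = w3, label = lab,
                            stringsAsFactors = FALSE)
    focal[u] <- (u - 1L) * 8L + f
  }
  truth <- structure(do.call(rbind, rows), class = c("sim_truth", "data.frame"))
  rownames(truth) <- NULL
  list(layout = layout, truth = truth, focal = focal)
}
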