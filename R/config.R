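#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic MNase-seq generator.
#' Defaults emulate budding-yeast chromatin: ~165 bp nucleosome repeat
#' length, ~147 bp protected fragments with gel-selection length noise,
#' 10 bp positional fuzziness, a modest uniform digestion background, and
#' four biological replicates sharing one underlying nucleosome map.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Number of genes tiled per chromosome.
#' @param spacing_mean Nucleosome repeat length (bp) of the planted grid.
#' @param fuzziness_sd Standard deviation (bp) of read centers around each
#'   planted dyad.
#' @param fragment_mean,fragment_sd Mean and s.d. (bp) of simulated
#'   mono-nucleosomal fragment lengths.
#' @param reads_per_nucleosome_mean Expected fragments per nucleosome per
#'   time point at unit occupancy weight (Poisson mean).
#' @param background_fraction Proportion of all emitted fragments whose
#'   midpoints are uniform over the chromosome, in `[0, 1)`.
#' @param reduce_fraction,retain_fraction,shift_fraction Proportions of
#'   planted nucleosomes assigned the corresponding perturbation label;
#'   their sum must not exceed 1 (the remainder is stable).
#' @param reduce_factor Occupancy multiplier in `(0, 1)` applied at 3 h to
#'   reduced nucleosomes.
#' @param retain_factor Occupancy multiplier `> 1` applied at 3 h to
#'   retained nucleosomes.
#' @param shift_magnitude Exact dyad displacement (bp) of shifted
#'   nucleosomes.
#' @param n_replicates Number of replicates sharing the planted truth.
#' @param paired Logical; emit paired fragments (lengths clipped to
#'   100-200 bp) or strand-bearing single-end reads.
#' @param read_length Single-end read length (bp); ignored when `paired`.
#' @param jitter Half-width (bp) of the uniform jitter applied to the
#'   planting grid.
#' @param promoter_bias Logical; preferentially assign the reduced label
#'   to promoter-overlapping dyads, emulating the promoter-biased
#'   occupancy loss seen under histone depletion.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 100000L,
                       n_genes = 20L,
                       spacing_mean = 165L,
                       fuzziness_sd = 10,
                       fragment_mean = 147L,
                       fragment_sd = 15,
                       reads_per_nucleosome_mean = 150,
                       background_fraction = 0.05,
                       reduce_fraction = 0.10,
                       retain_fraction = 0.02,
                       shift_fraction = 0.05,
                       reduce_factor = 0.5,
                       retain_factor = 2,
                       shift_magnitude = 30L,
                       n_replicates = 4L,
                       paired = TRUE,
                       read_length = 36L,
                       jitter = 10L,
                       promoter_bias = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    spacing_mean = as.integer(spacing_mean), fuzziness_sd = fuzziness_sd,
    fragment_mean = as.integer(fragment_mean), fragment_sd = fragment_sd,
    reads_per_nucleosome_mean = reads_per_nucleosome_mean,
    background_fraction = background_fraction,
    reduce_fraction = reduce_fraction, retain_fraction = retain_fraction,
    shift_fraction = shift_fraction, reduce_factor = reduce_factor,
    retain_factor = retain_factor, shift_magnitude = as.integer(shift_magnitude),
    n_replicates = as.integer(n_replicates), paired = isTRUE(paired),
    read_length = as.integer(read_length), jitter = as.integer(jitter),
    promoter_bias = isTRUE(promoter_bias)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("background_fraction", "reduce_fraction", "retain_fraction",
             "shift_fraction")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("`", p, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$background_fraction >= 1) {
    stop("`background_fraction` must be < 1", call. = FALSE)
  }
  frac_sum <- cfg$reduce_fraction + cfg$retain_fraction + cfg$shift_fraction
  if (frac_sum > 1 + 1e-12) {
    stop("reduce + retain + shift fractions exceed 1 (", frac_sum, ")",
         call. = FALSE)
  }
  if (cfg$spacing_mean <= 0) stop("`spacing_mean` must be positive", call. = FALSE)
  if (cfg$reduce_factor <= 0 || cfg$reduce_factor >= 1) {
    stop("`reduce_factor` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$retain_factor <= 1) stop("`retain_factor` must exceed 1", call. = FALSE)
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1) {
    stop("genome dimensions must be positive", call. = FALSE)
  }
  if (cfg$fuzziness_sd < 0 || cfg$fragment_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a flat key-value file
#'
#' One `key = value` pair per line; keys are the arguments of
#' [sim_config()].  Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
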