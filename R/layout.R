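#' Generate a synthetic genome layout
#'
#' Tiles each chromosome with `n_genes` non-overlapping transcribed
#' intervals on alternating strands.  The untranscribed gap preceding each
#' transcribed interval is that gene's promoter (the gap is assigned to the
#' downstream gene in coordinate order).  All coordinates are 0-based,
#' half-open.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genome_layout`: a list with `chrom_sizes`
#'   (named integer vector), `genes`, `transcribed`, `promoters` and
#'   `excluded` data.frames (`chrom`, `start`, `end`, plus `strand`,
#'   `tss`, `tts`, `gene_id` for genes).
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  chroms <- sprintf("chr%02d", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  genes_list <- vector("list", config$n_chroms)
  prom_list <- vector("list", config$n_chroms)

  if (config$n_genes > 0L) {
    slot <- config$chrom_length %/% config$n_genes
    if (slot < 200L) {
      stop("chrom_length too small to host n_genes genes (slot ", slot,
           " bp < 200 bp)", call. = FALSE)
    }
    for (ci in seq_len(config$n_chroms)) {
      slot_start <- (seq_len(config$n_genes) - 1L) * slot
      gap <- as.integer(round(runif(config$n_genes, 0.15, 0.35) * slot))
      g_start <- slot_start + gap
      g_end <- slot_start + slot
      strand <- rep_len(c("+", "-"), config$n_genes)
      tss <- ifelse(strand == "+", g_start, g_end - 1L)
      tts <- ifelse(strand == "+", g_end - 1L, g_start)
      genes_list[[ci]] <- data.frame(
        chrom = chroms[ci], start = g_start, end = g_end, strand = strand,
        tss = as.integer(tss), tts = as.integer(tts),
        gene_id = sprintf("%s_g%03d", chroms[ci], seq_len(config$n_genes)),
        stringsAsFactors = FALSE
      )
      prom_list[[ci]] <- data.frame(
        chrom = chroms[ci], start = slot_start, end = g_start,
        gene_id = genes_list[[ci]]$gene_id, stringsAsFactors = FALSE
      )
    }
  }

  genes <- if (config$n_genes > 0L) do.call(rbind, genes_list) else
    cbind(empty, data.frame(strand = character(), tss = integer(),
                            tts = integer(), gene_id = character()))
  promoters <- if (config$n_genes > 0L) do.call(rbind, prom_list) else
    cbind(empty, data.frame(gene_id = character()))

  structure(list(
    chrom_sizes = chrom_sizes,
    genes = genes,
    transcribed = genes[, c("chrom", "start", "end")],
    promoters = promoters,
    excluded = empty
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_sizes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

# membership of 0-based points in a set of half-open [start, end) intervals
# (intervals need not be disjoint)
points_in_intervals <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  if (nrow(intervals) == 0L || length(pos) == 0L) return(hit)
  for (cc in unique(chrom)) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    if (nrow(iv) == 0L) next
    sel <- which(chrom == cc)
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}
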