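#' Read and write chromosome sizes
#'
#' Two-column TSV (`chrom`, `length`), no header.
#'
#' @param path File path.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named integer vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  fwrite(data.table(chrom = names(chrom_sizes),
                    len = unname(chrom_sizes)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write fragment records as BED
#'
#' BED6: `chrom`, `start`, `end`, `name`, `score`, `strand`.  Paired
#' fragments carry strand `"."` (one record per fragment); single-end
#' reads carry `"+"`/`"-"`.
#'
#' @param fragments Data.frame with `chrom`, `start`, `end`, `strand`.
#' @param path File path.
#' @return The fragments data.frame (read) or `path` (write, invisibly).
#' @export
write_fragments_bed <- function(fragments, path) {
  fwrite(data.table(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end, name = "frag", score = 0L,
                    strand = fragments$strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("not a BED file: ", path, call. = FALSE)
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."
  data.frame(chrom = as.character(dt[[1L]]), start = as.integer(dt[[2L]]),
             end = as.integer(dt[[3L]]), strand = strand,
             paired = strand == ".", stringsAsFactors = FALSE)
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal value are collapsed; `NA` runs (missing data) are
#' omitted.  Zero runs are kept by default so the file round-trips the
#' dense track exactly.
#'
#' @param track A `density_track` or `annotation_track`.
#' @param path File path.
#' @param drop_zero Omit zero-valued runs.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  pieces <- lapply(names(track$values), function(cc) {
    v <- track$values[[cc]]
    r <- rle(ifelse(is.na(v), "NA", sprintf("%.8g", v)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (drop_zero) keep <- keep & r$values != "0"
    data.table(chrom = cc, start = starts[keep], end = ends[keep],
               value = r$values[keep])
  })
  fwrite(rbindlist(pieces), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a per-base track
#'
#' @param path File path.
#' @param chrom_sizes Named integer vector defining the genome.
#' @param default Fill value for positions not covered by any record
#'   (`NA` for annotation tracks, `0` for densities).
#' @return An `annotation_track`.
#' @export
read_bedgraph <- function(path, chrom_sizes, default = NA_real_) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  vals <- lapply(names(chrom_sizes), function(cc) {
    v <- rep(default, chrom_sizes[[cc]])
    d <- dt[dt$chrom == cc, ]
    if (nrow(d)) {
      for (i in seq_len(nrow(d))) {
        v[seq.int(d$start[i] + 1L, d$end[i])] <- d$value[i]
      }
    }
    v
  })
  names(vals) <- names(chrom_sizes)
  structure(list(values = vals, resolution = 1L), class = "annotation_track")
}

#' Write and read a planted truth table
#'
#' TSV with header (`chrom`, `dyad_t0`, `dyad_t3`, `weight_t0`,
#' `weight_t3`, `label`).
#'
#' @param truth A `sim_truth` data.frame.
#' @param path File path.
#' @return `path` (write, invisibly) or the truth data.frame (read).
#' @export
write_truth <- function(truth, path) {
  out <- as.data.frame(truth)
  out$weight_t0 <- sprintf("%.10g", out$weight_t0)
  out$weight_t3 <- sprintf("%.10g", out$weight_t3)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  dt <- as.data.frame(fread(path, sep = "\t"))
  structure(dt, class = c("sim_truth", "data.frame"))
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and
#'   optionally `gene_id`/`strand`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  name <- if ("gene_id" %in% names(intervals)) intervals$gene_id else "."
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  fwrite(data.table(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end, name = name, score = 0L,
                    strand = strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) out$gene_id <- as.character(dt[[4L]])
  if (ncol(dt) >= 6L) out$strand <- as.character(dt[[6L]])
  out
}
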