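#' Write nucleosome calls to disk
#'
#' The main file is a BED-derived TSV (`chrom`, `start`, `end`, `center`,
#' `protected_length`, `fuzziness`, `occupancy`, `n_members`,
#' `member_mean`, `member_var`, `peak_density`, `call_rank`, where
#' `start`/`end` are the half-open footprint).  Member read centers are
#' written to a sidecar file (`<path>.members.tsv`), one row per call,
#' keyed by call index, with space-separated coordinates; classification
#' needs them only through the summary statistics, so the sidecar mainly
#' serves genome-browser export and re-analysis.
#'
#' @param calls A `nucleosome_calls` data.frame.
#' @param path Output TSV path.
#' @param centers Optional [center_list()]; when given, the member
#'   sidecar is written.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, centers = NULL) {
  fb <- footprint_bounds(calls$center, calls$protected_length)
  out <- data.frame(chrom = calls$chrom, start = fb$start, end = fb$end,
                    center = calls$center,
                    protected_length = calls$protected_length,
                    fuzziness = sprintf("%.10g", calls$fuzziness),
                    occupancy = calls$occupancy,
                    n_members = calls$n_members,
                    member_mean = sprintf("%.10g", calls$member_mean),
                    member_var = sprintf("%.10g", calls$member_var),
                    peak_density = sprintf("%.10g", calls$peak_density),
                    call_rank = calls$call_rank,
                    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t")
  if (!is.null(centers)) {
    mem <- member_centers(calls, centers)
    side <- data.frame(
      call_index = seq_len(nrow(calls)),
      members = vapply(mem, paste, "", collapse = " "),
      stringsAsFactors = FALSE
    )
    fwrite(side, paste0(path, ".members.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Read nucleosome calls written by [write_calls()]
#'
#' @param path TSV path.
#' @return A `nucleosome_calls` data.frame.  If the member sidecar exists
#'   it is attached as the list attribute `member_centers`; otherwise the
#'   attribute is `NULL` and operations requiring raw member coordinates
#'   refuse the calls.
#' @export
read_calls <- function(path) {
  dt <- tryCatch(fread(path, sep = "\t"), error = function(e) {
    stop("failed to parse calls file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  need <- c("chrom", "center", "protected_length", "fuzziness", "occupancy",
            "n_members", "member_mean", "member_var", "peak_density",
            "call_rank")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("malformed calls file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  calls <- as.data.frame(dt[, need, with = FALSE])
  bad <- which(!is.finite(calls$center) | !is.finite(calls$protected_length))
  if (length(bad)) {
    stop("malformed row ", bad[1L] + 1L, " in ", path, call. = FALSE)
  }
  class(calls) <- c("nucleosome_calls", "data.frame")
  side_path <- paste0(path, ".members.tsv")
  if (file.exists(side_path)) {
    side <- fread(side_path, sep = "\t", colClasses = list(character = "members"))
    mem <- lapply(strsplit(side$members, " ", fixed = TRUE), function(s) {
      as.integer(s[nzchar(s)])
    })
    attr(calls, "member_centers") <- mem
  }
  calls
}
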