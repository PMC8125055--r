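#' Windowed AT-content scan of a genome
#'
#' Tiles each contig from offset 0 with fixed-width windows and computes the
#' AT fraction of each, the statistic used to visualise the AT landscape of a
#' GC-rich bacterial chromosome (default 500-bp windows with a 500-bp step).
#' A trailing fragment shorter than `window` is dropped so every window
#' carries an equal-width statistic. N bases are excluded from the
#' denominator; a window that is all N gets `at_fraction = NA`.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param window window width in bp.
#' @param step step between window starts in bp.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   at_fraction, n_count.
#' @export
compute_at_windows <- function(genome, window = 500L, step = 500L) {
  if (window < 1 || step < 1) stop("window and step must be >= 1")
  validate_genome(genome)
  out <- lapply(names(genome), function(ctg) {
    len <- length(genome[[ctg]])
    if (len < window) {
      return(NULL)
    }
    starts1 <- seq.int(1L, len - window + 1L, by = step) # 1-based view starts
    v <- Biostrings::Views(genome[[ctg]], start = starts1,
                           width = window)
    counts <- Biostrings::letterFrequency(v, letters = c("A", "T", "N"))
    n_count <- counts[, "N"]
    denom <- window - n_count
    at <- ifelse(denom > 0, (counts[, "A"] + counts[, "T"]) / denom, NA_real_)
    data.frame(contig = ctg, start = starts1 - 1L,
               end = starts1 - 1L + window, at_fraction = at,
               n_count = as.integer(n_count), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge consecutive AT-rich windows into regions
#'
#' Flags maximal runs of consecutive scan windows (adjacent scan positions on
#' the same contig) whose AT fraction is at least `threshold` and merges each
#' run into one interval. Windows with undefined AT fraction (all-N) never
#' qualify.
#'
#' @param windows output of [compute_at_windows()].
#' @param threshold AT fraction in (0, 1); the package default elsewhere is
#'   the genome-wide mean window AT plus two SDs (see [at_rich_threshold()]).
#' @return data.frame with columns contig, start, end, n_windows,
#'   mean_at_fraction.
#' @export
at_rich_regions <- function(windows, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_at_fraction = numeric(), stringsAsFactors = FALSE)
  if (is.null(windows) || nrow(windows) == 0) return(empty)
  windows <- windows[order(windows$contig, windows$start), , drop = FALSE]
  qual <- !is.na(windows$at_fraction) & windows$at_fraction >= threshold
  if (!any(qual)) return(empty)
  step <- infer_step(windows)
  # run id increments at every non-qualifying window, contig change, or gap
  # between scan positions larger than the step
  new_run <- c(TRUE, windows$contig[-1] != windows$contig[-nrow(windows)] |
                 diff(windows$start) != step)
  run <- cumsum(new_run | !qual)
  keep <- split(which(qual), run[qual])
  out <- lapply(keep, function(idx) {
    data.frame(contig = windows$contig[idx[1]],
               start = windows$start[idx[1]],
               end = windows$end[idx[length(idx)]],
               n_windows = length(idx),
               mean_at_fraction = mean(windows$at_fraction[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$contig, out$start), , drop = FALSE]
}

infer_step <- function(windows) {
  d <- diff(windows$start[windows$contig == windows$contig[1]])
  if (length(d) == 0) windows$end[1] - windows$start[1] else min(d)
}

#' Default AT-rich threshold: genome mean window AT + 2 SD
#'
#' The AT landscape itself does not come with a numeric definition of
#' "AT-rich"; this documented default flags windows two standard deviations
#' above the genome-wide mean of the window statistic.
#'
#' @param windows output of [compute_at_windows()].
#' @param n_sd number of standard deviations above the mean.
#' @return numeric threshold.
#' @export
at_rich_threshold <- function(windows, n_sd = 2) {
  at <- windows$at_fraction[!is.na(windows$at_fraction)]
  if (length(at) == 0) stop("no windows with defined AT fraction")
  mean(at) + n_sd * sd(at)
}

#' Write AT windows as TSV or bedGraph
#'
#' @param windows output of [compute_at_windows()].
#' @param path output file.
#' @param format "tsv" (full table) or "bedgraph" (browser track of
#'   at_fraction).
#' @return `path`, invisibly.
#' @export
write_at_windows <- function(windows, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ok <- !is.na(windows$at_fraction)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", windows$contig[ok],
                       windows$start[ok], windows$end[ok],
                       windows$at_fraction[ok]), path)
  }
  invisible(path)
}
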