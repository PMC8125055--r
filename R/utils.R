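#' napregulon: integrative mapping of a nucleoid-associated protein regulon
#'
#' The package implements the computational stages used to define the regulon
#' of a xenogeneic-silencing nucleoid-associated protein (NAP) in a GC-rich
#' bacterium: windowed AT-content scans, binding-site architecture and spacing
#' statistics, regulon calling from differential-expression tables,
#' direct-target assignment from promoter-window overlaps, promoter
#' AT-composition tests, cross-condition regulon comparison, and the Ra
#' surface-roughness statistic. All genomic coordinates are handled internally
#' as 0-based half-open intervals.
#'
#' @keywords internal
#' @importFrom stats rnorm runif rbinom rexp rgamma sd t.test quantile fivenum
#'   pt setNames median rmultinom
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

#' Round half away from zero
#'
#' Integer rounding where .5 always moves away from zero, the convention used
#' for all reported percentages (so 71.83 -> 72 and 45.97 -> 46, and 16.5
#' would round to 17 rather than to the even neighbour).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Percentage rounded half away from zero
#'
#' @param k numerator count.
#' @param n denominator count; `n = 0` yields 0.
#' @return integer percentage.
#' @export
#' @examples
#' pct_round(51, 71) # 72
#' pct_round(57, 124) # 46
pct_round <- function(k, n) {
  if (length(n) == 1L && n == 0) return(0)
  as.numeric(round_half_away(100 * k / n))
}

# Derive a child seed from a master seed so that regenerating one synthetic
# component does not shift the random streams of the others. Kept below 2^31.
derive_seed <- function(seed, component) {
  offsets <- c(genome = 1L, annotation = 2L, peaks = 3L, roughness = 4L,
               sampling = 5L, permutation = 6L)
  if (!component %in% names(offsets)) {
    stop("unknown seed component: ", component)
  }
  (as.integer(seed) %% 1000003L) * 2011L + offsets[[component]] * 10007L
}

# Internal validator helpers -------------------------------------------------

assert_genes <- function(genes) {
  needed <- c("gene_id", "contig", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(needed %in% names(genes))) {
    stop("gene annotation must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("gene intervals must satisfy 0 <= start < end (0-based half-open)")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

assert_peaks <- function(peaks) {
  needed <- c("peak_id", "contig", "start", "end", "midpoint")
  if (!is.data.frame(peaks) || !all(needed %in% names(peaks))) {
    stop("peaks must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (any(peaks$start >= peaks$end)) stop("peak intervals must have start < end")
  invisible(peaks)
}
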