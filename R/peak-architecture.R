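#' Classify binding sites by gene-pair architecture
#'
#' Each site is reduced to a reference point (its midpoint by default) and
#' classified against the gene models of its contig:
#' \itemize{
#'   \item \strong{intragenic} — the point lies within a gene body (ties go to
#'     the containing gene with the smallest start);
#'   \item \strong{intergenic_tandem} — flanking genes on the same strand;
#'   \item \strong{intergenic_convergent} — flanks (+,-), i.e. 3' ends facing
#'     the site;
#'   \item \strong{intergenic_divergent} — flanks (-,+), i.e. 5' ends facing
#'     the site;
#'   \item \strong{terminal} — only one flank exists on the contig.
#' }
#' The left flank is the gene with the greatest end at or before the point,
#' the right flank the gene with the smallest start after it.
#'
#' @param peaks peak data.frame (see [read_bed()]).
#' @param genes annotation data.frame (see [read_gff3()]).
#' @param point which coordinate represents a site: "midpoint", "start" or
#'   "end".
#' @param overlap_mode "midpoint" (default: a site is intragenic iff its
#'   reference point falls in a gene body) or "any" (intragenic iff the site
#'   interval overlaps any gene body by >= 1 bp).
#' @return data.frame with columns peak_id, category, left_gene_id,
#'   right_gene_id (NA where not applicable).
#' @export
classify_peaks <- function(peaks, genes, point = c("midpoint", "start", "end"),
                           overlap_mode = c("midpoint", "any")) {
  point <- match.arg(point)
  overlap_mode <- match.arg(overlap_mode)
  assert_peaks(peaks)
  assert_genes(genes)
  missing_ctg <- setdiff(unique(peaks$contig), unique(genes$contig))
  if (length(missing_ctg)) {
    stop("no annotated genes on contig(s): ",
         paste(missing_ctg, collapse = ", "))
  }
  pos <- switch(point, midpoint = peaks$midpoint, start = peaks$start,
                end = peaks$end - 1L)
  out <- data.frame(peak_id = peaks$peak_id,
                    category = NA_character_,
                    left_gene_id = NA_character_,
                    right_gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (ctg in unique(peaks$contig)) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    idx <- which(peaks$contig == ctg)
    for (i in idx) {
      p <- pos[i]
      if (overlap_mode == "midpoint") {
        inside <- which(g$start <= p & p < g$end)
      } else {
        inside <- which(g$start < peaks$end[i] & peaks$start[i] < g$end)
      }
      if (length(inside)) {
        hit <- inside[which.min(g$start[inside])]
        out$category[i] <- "intragenic"
        out$left_gene_id[i] <- g$gene_id[hit]
        next
      }
      left <- which(g$end <= p)
      right <- which(g$start > p)
      l <- if (length(left)) left[which.max(g$end[left])] else NA_integer_
      r <- if (length(right)) right[which.min(g$start[right])] else NA_integer_
      if (is.na(l) || is.na(r)) {
        out$category[i] <- "terminal"
        flank <- if (is.na(l)) r else l
        if (is.na(l)) out$right_gene_id[i] <- g$gene_id[flank]
        else out$left_gene_id[i] <- g$gene_id[flank]
        next
      }
      out$left_gene_id[i] <- g$gene_id[l]
      out$right_gene_id[i] <- g$gene_id[r]
      key <- paste0(g$strand[l], g$strand[r])
      out$category[i] <- switch(key,
        "++" = "intergenic_tandem",
        "--" = "intergenic_tandem",
        "+-" = "intergenic_convergent",
        "-+" = "intergenic_divergent")
    }
  }
  out
}

#' Tabulate architecture categories
#'
#' @param contexts output of [classify_peaks()].
#' @return data.frame with columns category, count, percentage (integer,
#'   rounded half away from zero) plus an `intergenic` aggregate row covering
#'   the three intergenic orientations.
#' @export
architecture_fractions <- function(contexts) {
  if (is.null(contexts) || nrow(contexts) == 0) stop("no peak contexts given")
  cats <- c("intragenic", "intergenic_tandem", "intergenic_convergent",
            "intergenic_divergent", "terminal")
  counts <- vapply(cats, function(k) sum(contexts$category == k), integer(1))
  n <- nrow(contexts)
  inter <- sum(counts[c("intergenic_tandem", "intergenic_convergent",
                        "intergenic_divergent")])
  out <- data.frame(
    category = c(cats, "intergenic"),
    count = c(counts, inter),
    percentage = c(vapply(counts, pct_round, numeric(1), n = n),
                   pct_round(inter, n)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Nearest-neighbour distances between binding sites
#'
#' Per contig, sites are ordered by midpoint and each contributes its
#' distance (midpoint to midpoint) to the closest other site; distances are
#' pooled across contigs. Contigs with fewer than two sites contribute
#' nothing; it is an error if no contig has two.
#'
#' @param peaks peak data.frame.
#' @param circular if TRUE, treat each contig as circular with length from
#'   `contig_lengths` and allow wraparound distances.
#' @param contig_lengths named integer vector, required when `circular`.
#' @return integer vector of distances (one per contributing site).
#' @export
nearest_peak_distances <- function(peaks, circular = FALSE,
                                   contig_lengths = NULL) {
  assert_peaks(peaks)
  if (circular && is.null(contig_lengths)) {
    stop("circular mode needs contig_lengths")
  }
  by_ctg <- split(peaks$midpoint, peaks$contig)
  dists <- unlist(lapply(names(by_ctg), function(ctg) {
    m <- by_ctg[[ctg]]
    if (length(m) < 2) return(NULL)
    m <- sort(m)
    gaps <- diff(m)
    if (circular) {
      wrap <- contig_lengths[[ctg]] - (m[length(m)] - m[1])
      lo <- c(wrap, gaps)   # gap before each site
      hi <- c(gaps, wrap)   # gap after each site
    } else {
      lo <- c(Inf, gaps)
      hi <- c(gaps, Inf)
    }
    pmin(lo, hi)
  }), use.names = FALSE)
  if (length(dists) == 0) {
    stop("need at least two sites on some contig to compute spacing")
  }
  as.integer(dists)
}

#' Quartiles of a spacing distribution
#'
#' The default "hinges" method takes Q1 as the middle number between the
#' smallest value and the median and Q3 as the middle value between the
#' median and the largest (Tukey hinges, [stats::fivenum()]); "linear" uses
#' interpolated sample quantiles ([stats::quantile()] type 6).
#'
#' @param x numeric vector.
#' @param method "hinges" or "linear".
#' @return named numeric vector c(q1, median, q3).
#' @export
spacing_quartiles <- function(x, method = c("hinges", "linear")) {
  method <- match.arg(method)
  if (length(x) == 0) stop("empty distance vector")
  q <- if (method == "hinges") {
    fivenum(x)[2:4]
  } else {
    unname(quantile(x, c(0.25, 0.5, 0.75), type = 6))
  }
  setNames(q, c("q1", "median", "q3"))
}

#' Bridged-gene estimate from the spacing interquartile range
#'
#' Converts the interquartile range of nearest-site distances into the number
#' of average-length genes an oligomerising NAP could bridge: with an average
#' gene of `avg_gene_len` bp, a loop spanning q bp contains floor(q /
#' avg_gene_len) whole genes.
#'
#' @param q1,q3 first and third quartile of the spacing distribution, bp.
#' @param avg_gene_len average gene length in bp (default 946, the
#'   M. smegmatis genome-wide average).
#' @return named integer vector c(min_genes, max_genes).
#' @export
bridged_gene_range <- function(q1, q3, avg_gene_len = 946) {
  if (!(q1 > 0 && q3 >= q1)) stop("need 0 < q1 <= q3")
  if (avg_gene_len <= 0) stop("avg_gene_len must be positive")
  c(min_genes = as.integer(q1 %/% avg_gene_len),
    max_genes = as.integer(q3 %/% avg_gene_len))
}

#' Spacing summary of a peak set
#'
#' Convenience wrapper: nearest-neighbour distances, quartiles and the
#' bridged-gene estimate in one list.
#'
#' @inheritParams nearest_peak_distances
#' @inheritParams spacing_quartiles
#' @inheritParams bridged_gene_range
#' @return list(distances, q1, median, q3, min_genes, max_genes).
#' @export
spacing_summary <- function(peaks, method = c("hinges", "linear"),
                            avg_gene_len = 946) {
  d <- nearest_peak_distances(peaks)
  q <- spacing_quartiles(d, method)
  b <- bridged_gene_range(q[["q1"]], q[["q3"]], avg_gene_len)
  list(distances = d, q1 = q[["q1"]], median = q[["median"]], q3 = q[["q3"]],
       min_genes = b[["min_genes"]], max_genes = b[["max_genes"]])
}
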