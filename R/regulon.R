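#' log2 fold-change threshold for a fold cutoff
#'
#' @param fold fold change (> 0); fold = 3 gives the 1.585 cutoff used to
#'   define the regulon ("at least 3 times up or down").
#' @return log2(fold), rounded to 3 decimals for reporting.
#' @export
lfc_threshold_for_fold <- function(fold) {
  if (!is.numeric(fold) || any(fold <= 0)) stop("fold must be > 0")
  round(log2(fold), 3)
}

#' Call a NAP regulon from a differential-expression table
#'
#' A gene belongs to the regulon when |log2fc| is strictly greater than
#' `lfc_threshold` (default log2(3) = 1.585, i.e. at least a 3-fold change)
#' and, unless disabled, adj_p <= `p_threshold`. Fold changes are mutant vs
#' wild type, so a positive log2fc (higher in the deletion mutant) means the
#' NAP represses the gene (`repressed_by_nap`) and a negative one means it
#' activates it (`activated_by_nap`).
#'
#' @param de_records DE data.frame (gene_id, log2fc, adj_p, condition).
#' @param condition condition label to select.
#' @param lfc_threshold strict |log2fc| cutoff.
#' @param p_threshold adjusted-p cutoff; set to NULL (or NA) to apply the
#'   fold-change rule alone.
#' @return object of class `regulon`: list(condition, entries) where entries
#'   is a data.frame (gene_id, log2fc, adj_p, direction, mode,
#'   supporting_peaks). Modes are "indirect" until
#'   [assign_direct_targets()] is run.
#' @export
call_regulon <- function(de_records, condition, lfc_threshold = 1.585,
                         p_threshold = 0.05) {
  de <- de_records[de_records$condition == condition, , drop = FALSE]
  if (nrow(de) == 0) stop("no DE records for condition '", condition, "'")
  keep <- abs(de$log2fc) > lfc_threshold
  if (!is.null(p_threshold) && !is.na(p_threshold)) {
    keep <- keep & de$adj_p <= p_threshold
  }
  de <- de[keep, , drop = FALSE]
  entries <- data.frame(
    gene_id = de$gene_id,
    log2fc = de$log2fc,
    adj_p = de$adj_p,
    direction = ifelse(de$log2fc > 0, "repressed_by_nap", "activated_by_nap"),
    mode = rep("indirect", nrow(de)),
    supporting_peaks = rep("", nrow(de)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(entries$gene_id)) {
    stop("duplicate gene_id within condition '", condition, "'")
  }
  structure(list(condition = condition, entries = entries),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  s <- regulon_summary(x)
  cat("NAP regulon (condition: ", x$condition, ")\n", sep = "")
  cat("  genes: ", s$n_total, " (", s$n_repressed, " repressed, ",
      s$n_activated, " activated by the NAP)\n", sep = "")
  cat("  direct targets: ", s$n_direct, " (", s$n_direct_repressed,
      " repressed, ", s$n_direct_activated, " activated)\n", sep = "")
  invisible(x)
}

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the `upstream` bp immediately 5' of its start
#' codon: `[start - upstream, start)` for '+' genes and `[end, end +
#' upstream)` for '-' genes (whose start codon sits at the high-coordinate
#' end), clipped to the contig.
#'
#' @param genes annotation data.frame.
#' @param upstream window size in bp (default 150).
#' @param contig_lengths optional named vector used to clip '-'-strand
#'   windows at contig ends.
#' @return data.frame with columns gene_id, contig, start, end (0-based
#'   half-open), strand.
#' @export
promoter_windows <- function(genes, upstream = 150L, contig_lengths = NULL) {
  assert_genes(genes)
  if (upstream < 1) stop("upstream must be >= 1")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - upstream), genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream)
  if (!is.null(contig_lengths)) {
    end <- pmin(end, unname(contig_lengths[genes$contig]))
  }
  data.frame(gene_id = genes$gene_id, contig = genes$contig,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Assign direct vs indirect targets from binding-site overlaps
#'
#' A regulon gene is a direct target when at least one binding-site interval
#' overlaps its promoter window (the `upstream` bp 5' of the start codon) by
#' at least 1 bp; all overlapping sites are recorded as supporting peaks.
#' Membership of the regulon is never changed, only modes.
#'
#' @param regulon a `regulon` object from [call_regulon()].
#' @param peaks peak data.frame.
#' @param genes annotation data.frame; every regulon gene must be present.
#' @param upstream promoter window size in bp.
#' @param contig_lengths optional clipping lengths, see [promoter_windows()].
#' @return the regulon with `mode` and `supporting_peaks` filled in.
#' @export
assign_direct_targets <- function(regulon, peaks, genes, upstream = 150L,
                                  contig_lengths = NULL) {
  stopifnot(inherits(regulon, "regulon"))
  assert_peaks(peaks)
  missing <- setdiff(regulon$entries$gene_id, genes$gene_id)
  if (length(missing)) {
    stop("regulon gene(s) missing from annotation: ",
         paste(missing, collapse = ", "))
  }
  g <- genes[match(regulon$entries$gene_id, genes$gene_id), , drop = FALSE]
  prom <- promoter_windows(g, upstream, contig_lengths)
  entries <- regulon$entries
  entries$mode <- "indirect"
  entries$supporting_peaks <- ""
  for (ctg in unique(prom$contig)) {
    pi <- which(prom$contig == ctg & prom$end > prom$start)
    ki <- which(peaks$contig == ctg)
    if (!length(pi) || !length(ki)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(prom$start[pi] + 1L, prom$end[pi]),
      IRanges::IRanges(peaks$start[ki] + 1L, peaks$end[ki]),
      minoverlap = 1L
    )
    if (!length(hits)) next
    by_prom <- split(ki[S4Vectors::subjectHits(hits)],
                     pi[S4Vectors::queryHits(hits)])
    for (j in names(by_prom)) {
      i <- as.integer(j)
      entries$mode[i] <- "direct"
      entries$supporting_peaks[i] <-
        paste(peaks$peak_id[by_prom[[j]]], collapse = ";")
    }
  }
  regulon$entries <- entries
  regulon
}

#' Summary counts and percentages of a regulon
#'
#' Reports both vocabularies used for direction: genes repressed/activated by
#' the NAP, and the equivalent fraction whose transcription decreased in the
#' deletion mutant (identical to the activated fraction under the fixed sign
#' convention). Percentages are rounded half away from zero.
#'
#' @param regulon a `regulon` object.
#' @return list with n_total, n_repressed, n_activated, pct_activated,
#'   pct_with_decreased_transcription_in_mutant, n_direct,
#'   n_direct_repressed, n_direct_activated.
#' @export
regulon_summary <- function(regulon) {
  stopifnot(inherits(regulon, "regulon"))
  e <- regulon$entries
  n <- nrow(e)
  n_rep <- sum(e$direction == "repressed_by_nap")
  n_act <- sum(e$direction == "activated_by_nap")
  direct <- e$mode == "direct"
  list(
    n_total = n,
    n_repressed = n_rep,
    n_activated = n_act,
    pct_activated = pct_round(n_act, n),
    pct_with_decreased_transcription_in_mutant = pct_round(n_act, n),
    n_direct = sum(direct),
    n_direct_repressed = sum(direct & e$direction == "repressed_by_nap"),
    n_direct_activated = sum(direct & e$direction == "activated_by_nap")
  )
}

#' Compare two regulons by gene membership
#'
#' @param a,b `regulon` objects (e.g. optimal-oxygen vs hypoxia).
#' @return object of class `regulon_comparison`: list(shared, unique_a,
#'   unique_b, n_shared, n_unique_a, n_unique_b, condition_a, condition_b).
#' @export
compare_regulons <- function(a, b) {
  stopifnot(inherits(a, "regulon"), inherits(b, "regulon"))
  ga <- a$entries$gene_id
  gb <- b$entries$gene_id
  shared <- intersect(ga, gb)
  structure(list(
    shared = shared,
    unique_a = setdiff(ga, gb),
    unique_b = setdiff(gb, ga),
    n_shared = length(shared),
    n_unique_a = length(setdiff(ga, gb)),
    n_unique_b = length(setdiff(gb, ga)),
    condition_a = a$condition,
    condition_b = b$condition
  ), class = "regulon_comparison")
}

#' @export
print.regulon_comparison <- function(x, ...) {
  cat("Regulon comparison: ", x$condition_a, " vs ", x$condition_b, "\n",
      sep = "")
  cat("  shared: ", x$n_shared, "; unique to ", x$condition_a, ": ",
      x$n_unique_a, "; unique to ", x$condition_b, ": ", x$n_unique_b, "\n",
      sep = "")
  invisible(x)
}

#' Write a regulon to TSV
#'
#' @param regulon a `regulon` object.
#' @param path output TSV (gene_id, condition, log2fc, adj_p, direction,
#'   mode, supporting_peaks).
#' @return `path`, invisibly.
#' @export
write_regulon <- function(regulon, path) {
  stopifnot(inherits(regulon, "regulon"))
  out <- cbind(regulon$entries[, "gene_id", drop = FALSE],
               condition = regulon$condition,
               regulon$entries[, c("log2fc", "adj_p", "direction", "mode",
                                   "supporting_peaks")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
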