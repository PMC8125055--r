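#' Intersect replicate peak sets
#'
#' Reproducible sites: intervals of `a` that overlap some interval of `b` by
#' at least `min_overlap` bp. For each retained site the overlapping region
#' (union of its intersections with `b`) and the total overlap are reported.
#'
#' @param a,b peak data.frames in the same coordinate space.
#' @param min_overlap minimum overlap in bp.
#' @return the overlapping subset of `a` with extra columns overlap_start,
#'   overlap_end, overlap_bp.
#' @export
intersect_replicate_peaks <- function(a, b, min_overlap = 1L) {
  assert_peaks(a)
  assert_peaks(b)
  keep <- logical(nrow(a))
  ov_start <- rep(NA_integer_, nrow(a))
  ov_end <- rep(NA_integer_, nrow(a))
  ov_bp <- rep(0L, nrow(a))
  for (ctg in intersect(unique(a$contig), unique(b$contig))) {
    ai <- which(a$contig == ctg)
    bi <- which(b$contig == ctg)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi]),
      minoverlap = as.integer(min_overlap)
    )
    if (!length(hits)) next
    for (q in unique(S4Vectors::queryHits(hits))) {
      i <- ai[q]
      js <- bi[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]]
      os <- pmax(a$start[i], b$start[js])
      oe <- pmin(a$end[i], b$end[js])
      keep[i] <- TRUE
      ov_start[i] <- min(os)
      ov_end[i] <- max(oe)
      ov_bp[i] <- sum(oe - os)
    }
  }
  out <- a[keep, , drop = FALSE]
  out$overlap_start <- ov_start[keep]
  out$overlap_end <- ov_end[keep]
  out$overlap_bp <- ov_bp[keep]
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' All tunables of the integrative analysis with their defaults: 500-bp
#' AT windows with a 500-bp step, a strict |log2FC| > log2(3) = 1.585 regulon
#' cutoff with adj_p <= 0.05, a 150-bp promoter window, Tukey-hinge spacing
#' quartiles over a 946-bp average gene, Welch promoter-composition test
#' against 50 random promoters.
#'
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    window = 500L, step = 500L,
    at_rich_sd = 2,
    lfc_threshold = 1.585, p_threshold = 0.05,
    upstream = 150L,
    quartile_method = "hinges", avg_gene_len = 946,
    n_random_promoters = 50L, at_test = "welch_t",
    overlap_mode = "midpoint",
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full integrative analysis
#'
#' Executes every stage in order on in-memory inputs: AT-landscape scan,
#' binding-site architecture classification, nearest-site spacing with the
#' bridged-gene estimate, regulon calling, direct-target assignment,
#' promoter AT comparison against a random background, and (when profiles
#' are given) the roughness comparison. Deterministic given the
#' configuration and seed.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param genes annotation data.frame.
#' @param peaks peak data.frame.
#' @param de DE data.frame.
#' @param condition condition label to analyse.
#' @param roughness optional line-profile data.frame with a `group` column
#'   naming exactly two groups.
#' @param config list from [default_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   TSV along with a run manifest.
#' @return list of stage results: at_windows, at_rich, contexts,
#'   architecture, spacing, regulon, regulon_summary, promoter_comparison,
#'   roughness (or NULL), config.
#' @export
run_pipeline <- function(genome, genes, peaks, de, condition,
                         roughness = NULL, config = default_config(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  clens <- setNames(Biostrings::width(genome), names(genome))

  at_windows <- stage("at_landscape",
                      compute_at_windows(genome, config$window, config$step))
  at_rich <- stage("at_landscape", at_rich_regions(
    at_windows, at_rich_threshold(at_windows, config$at_rich_sd)))

  contexts <- stage("peak_architecture",
                    classify_peaks(peaks, genes,
                                   overlap_mode = config$overlap_mode))
  architecture <- stage("peak_architecture", architecture_fractions(contexts))
  spacing <- stage("peak_architecture",
                   spacing_summary(peaks, method = config$quartile_method,
                                   avg_gene_len = config$avg_gene_len))

  regulon <- stage("regulon_integration",
                   call_regulon(de, condition, config$lfc_threshold,
                                config$p_threshold))
  regulon <- stage("regulon_integration",
                   assign_direct_targets(regulon, peaks, genes,
                                         config$upstream, clens))
  rsummary <- regulon_summary(regulon)

  # promoter composition is contrasted for the directly regulated genes (the
  # binding-site-supported ones); all regulon genes are used if none are direct
  direct_ids <- regulon$entries$gene_id[regulon$entries$mode == "direct"]
  if (length(direct_ids) == 0) direct_ids <- regulon$entries$gene_id
  reg_genes <- genes[genes$gene_id %in% direct_ids, , drop = FALSE]
  prom_cmp <- stage("promoter_stats", {
    reg_prom <- extract_promoters(reg_genes, genome, config$upstream,
                                  label = "regulated")
    rnd_prom <- sample_random_promoters(
      genes, genome, n = config$n_random_promoters,
      seed = derive_seed(config$seed, "sampling"),
      exclude = regulon$entries$gene_id, upstream = config$upstream)
    compare_at(reg_prom, rnd_prom, test = config$at_test,
               seed = derive_seed(config$seed, "permutation"))
  })

  rough_cmp <- NULL
  if (!is.null(roughness)) {
    rough_cmp <- stage("surface_roughness", {
      groups <- unique(roughness$group)
      if (length(groups) != 2) stop("roughness data must have two groups")
      ra <- lapply(groups, function(g)
        cell_ra(roughness[roughness$group == g, , drop = FALSE]))
      c(list(group_a = groups[1], group_b = groups[2]),
        compare_roughness_groups(ra[[1]], ra[[2]]))
    })
  }

  report <- list(at_windows = at_windows, at_rich = at_rich,
                 contexts = contexts, architecture = architecture,
                 spacing = spacing, regulon = regulon,
                 regulon_summary = rsummary,
                 promoter_comparison = prom_cmp, roughness = rough_cmp,
                 config = config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to a directory
#'
#' @param report list returned by [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$at_windows, "at_windows.tsv")
  tsv(report$at_rich, "at_rich_regions.tsv")
  tsv(report$contexts, "peak_contexts.tsv")
  tsv(report$architecture, "architecture_fractions.tsv")
  tsv(data.frame(distance_bp = report$spacing$distances), "spacing_distances.tsv")
  write_regulon(report$regulon, file.path(out_dir, "regulon.tsv"))
  tsv(as.data.frame(report$regulon_summary), "regulon_summary.tsv")
  pc <- report$promoter_comparison
  tsv(data.frame(mean_at_regulated = pc$mean_at_a,
                 mean_at_random = pc$mean_at_b,
                 difference = pc$difference, statistic = pc$statistic,
                 p_value = pc$p_value, test = pc$test,
                 n_regulated = pc$n_a, n_random = pc$n_b),
      "promoter_at_comparison.tsv")
  write_at_profiles(pc, file.path(out_dir, "promoter_at_profiles.tsv"),
                    labels = c("regulated", "random"))
  if (!is.null(report$roughness)) {
    tsv(as.data.frame(report$roughness), "roughness_comparison.tsv")
  }
  manifest <- c(report$config,
                list(spacing_q1 = report$spacing$q1,
                     spacing_median = report$spacing$median,
                     spacing_q3 = report$spacing$q3,
                     bridged_min_genes = report$spacing$min_genes,
                     bridged_max_genes = report$spacing$max_genes))
  write_manifest(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
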