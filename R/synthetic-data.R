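#' Simulate a GC-rich bacterial genome with planted AT-rich islands
#'
#' Bases are drawn i.i.d. at the baseline composition (default 67% GC, the
#' mycobacterial regime) outside islands; inside each island the AT fraction
#' is elevated to `island_at`, emulating horizontally acquired AT-rich
#' regions. Islands are non-overlapping; placement is rejection-sampled and
#' errors out if they cannot be placed.
#'
#' @param contig_len length of each contig in bp.
#' @param n_contigs number of contigs.
#' @param baseline_gc genome-background GC fraction.
#' @param n_islands islands per contig.
#' @param island_len island length in bp.
#' @param island_at AT fraction inside islands; must exceed the baseline AT
#'   fraction `1 - baseline_gc`.
#' @param seed RNG seed.
#' @return list(genome = [Biostrings::DNAStringSet],
#'   islands = data.frame(contig, start, end), seed).
#' @export
simulate_genome <- function(contig_len = 200000L, n_contigs = 1L,
                            baseline_gc = 0.67, n_islands = 10L,
                            island_len = 2000L, island_at = 0.55,
                            seed = 1L) {
  baseline_at <- 1 - baseline_gc
  if (n_islands > 0 && island_at <= baseline_at) {
    stop("island_at must exceed the baseline AT fraction ", baseline_at)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(n, at) {
    sample(c("A", "T", "C", "G"), n, replace = TRUE,
           prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
  }
  islands_all <- list()
  seqs <- character(n_contigs)
  for (k in seq_len(n_contigs)) {
    ctg <- sprintf("contig_%02d", k)
    starts <- place_nonoverlapping(contig_len, rep(island_len, n_islands))
    bases <- draw(contig_len, baseline_at)
    for (s in starts) {
      bases[(s + 1):(s + island_len)] <- draw(island_len, island_at)
    }
    seqs[k] <- paste(bases, collapse = "")
    if (n_islands > 0) {
      islands_all[[k]] <- data.frame(contig = ctg, start = starts,
                                     end = starts + island_len,
                                     stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("contig_%02d", seq_len(n_contigs))
  islands <- if (length(islands_all)) {
    x <- do.call(rbind, islands_all)
    x[order(x$contig, x$start), , drop = FALSE]
  } else {
    data.frame(contig = character(), start = integer(), end = integer())
  }
  list(genome = genome, islands = islands, seed = seed)
}

# Rejection-sample non-overlapping 0-based start positions for intervals of
# the given lengths on [0, space_len).
place_nonoverlapping <- function(space_len, lengths, max_tries = 2000L) {
  if (length(lengths) == 0) return(integer())
  if (sum(lengths) > space_len) stop("islands cannot fit in the contig")
  placed_start <- integer()
  placed_end <- integer()
  for (len in lengths) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(space_len - len + 1L, 1L) - 1L
      if (!any(s < placed_end & placed_start < s + len)) {
        placed_start <- c(placed_start, s)
        placed_end <- c(placed_end, s + len)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place islands without overlap")
  }
  sort(placed_start)
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes are packed along each contig with positive intergenic gaps. Lengths
#' are drawn around `mean_gene_len` (default 946 bp, the M. smegmatis
#' genome-wide average) and the remaining space is split into random
#' positive gaps, giving the high coding density typical of bacterial
#' chromosomes. When `islands` is supplied, gaps falling inside the AT-rich
#' islands receive `island_gap_boost` times the gap-space allocation:
#' horizontally acquired islands carry sparser annotation, which is what
#' leaves room for the extensive intergenic NAP binding observed there.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param n_genes total number of genes (split across contigs by length).
#' @param mean_gene_len mean gene length in bp.
#' @param sd_gene_len SD of gene length (lengths are clipped at
#'   `min_gene_len`).
#' @param min_gene_len shortest allowed gene.
#' @param strand_mix probability that a gene is on the '+' strand.
#' @param islands optional island table (contig, start, end) from
#'   [simulate_genome()].
#' @param island_gap_boost multiplier on the expected intergenic gap width
#'   inside islands.
#' @param seed RNG seed.
#' @return data.frame annotation (gene_id, contig, start, end, strand).
#' @export
simulate_annotation <- function(genome, n_genes = 200L, mean_gene_len = 946L,
                                sd_gene_len = 250L, min_gene_len = 150L,
                                strand_mix = 0.5, islands = NULL,
                                island_gap_boost = 8, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- Biostrings::width(genome)
  per_ctg <- round(n_genes * lens / sum(lens))
  per_ctg[length(per_ctg)] <- n_genes - sum(per_ctg[-length(per_ctg)])
  rows <- list()
  gene_no <- 0L
  for (k in seq_along(genome)) {
    ng <- per_ctg[k]
    if (ng == 0) next
    glens <- pmax(min_gene_len, round(rnorm(ng, mean_gene_len, sd_gene_len)))
    # pin the total coding space so the intergenic budget does not drift
    # with the length draw (coding density is a fixed property of a genome)
    glens <- pmax(min_gene_len,
                  as.integer(round(glens * (ng * mean_gene_len) / sum(glens))))
    slack <- lens[k] - sum(glens) - (ng + 1L) # min gap of 1 bp each
    if (slack < 0) {
      stop("genes do not fit on contig ", names(genome)[k],
           " with positive intergenic gaps")
    }
    gap_w <- rep(1, ng + 1L)
    if (!is.null(islands) && nrow(islands) > 0) {
      isl <- islands[islands$contig == names(genome)[k], , drop = FALSE]
      if (nrow(isl) > 0) {
        # provisional gap positions under uniform allocation locate which
        # gaps fall inside an island; those get boosted gap space
        prov <- cumsum(c(0, glens)) +
          round(seq(0, slack, length.out = ng + 1L)) + seq_len(ng + 1L)
        in_isl <- vapply(prov, function(p)
          any(isl$start <= p & p < isl$end), logical(1))
        gap_w[in_isl] <- island_gap_boost
      }
    }
    extra <- as.vector(rmultinom(1, slack, gap_w))
    gaps <- 1L + extra
    starts <- cumsum(c(gaps[1], glens[-ng] + gaps[2:ng]))
    rows[[k]] <- data.frame(
      gene_id = sprintf("gene_%04d", gene_no + seq_len(ng)),
      contig = names(genome)[k],
      start = as.integer(starts),
      end = as.integer(starts + glens),
      strand = ifelse(runif(ng) < strand_mix, "+", "-"),
      stringsAsFactors = FALSE
    )
    gene_no <- gene_no + ng
  }
  genes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  assert_genes(genes)
  genes
}

#' Simulate ChIP binding sites and a matched DE table with planted truth
#'
#' Plants three classes of binding sites and a differential-expression table
#' over the full annotation:
#' \itemize{
#'   \item \strong{direct targets} (`n_direct` genes): one site wholly inside
#'     the gene's promoter window and a log2 fold change whose magnitude
#'     strictly exceeds `lfc_threshold` (repressed — positive in the deletion
#'     mutant — with probability `prop_repressed`, emulating a silencer);
#'   \item \strong{indirect targets} (`n_indirect` genes): an above-threshold
#'     fold change but no promoter site;
#'   \item \strong{background sites} (`n_background`): placed preferentially
#'     in AT-rich intergenic gaps (selection probability proportional to
#'     exp(`at_weight` * gap AT fraction)), with a fraction placed inside
#'     gene bodies, and never touching the promoter window of any regulated
#'     gene.
#' }
#' Noise genes get small fold changes (|log2fc| capped at 1.5) and uniform
#' adjusted p-values, so the planted regulon is exactly recoverable.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param genes annotation data.frame.
#' @param n_direct,n_indirect,n_background class sizes.
#' @param frac_intragenic fraction of background sites placed inside genes.
#' @param prop_repressed probability a regulated gene is repressed by the NAP.
#' @param lfc_threshold regulon fold-change cutoff the planted effects must
#'   exceed.
#' @param upstream promoter window size in bp.
#' @param peak_width_range inclusive range of site widths in bp.
#' @param at_weight exponential weight of gap AT content for background
#'   placement.
#' @param prefer_at_promoters when TRUE (default) direct targets are drawn
#'   with probability proportional to exp(`promoter_at_weight` * promoter AT
#'   fraction), emulating a xenogeneic silencer whose direct targets carry
#'   AT-rich promoters; FALSE draws them uniformly.
#' @param promoter_at_weight exponential weight of promoter AT content for
#'   direct-target selection.
#' @param min_separation minimum distance in bp between planted sites (sites
#'   are pairwise disjoint with at least this gap).
#' @param condition condition label for the DE table.
#' @param seed RNG seed.
#' @return list(peaks, de, truth) where truth is a list(direct_targets,
#'   indirect_targets, peak_classes, lfc_threshold, condition, seed).
#' @export
simulate_peaks_and_de <- function(genome, genes, n_direct = 30L,
                                  n_indirect = 15L, n_background = 150L,
                                  frac_intragenic = 0.15,
                                  prop_repressed = 0.9,
                                  lfc_threshold = 1.585, upstream = 150L,
                                  peak_width_range = c(15L, 40L),
                                  at_weight = 12, prefer_at_promoters = TRUE,
                                  promoter_at_weight = 10,
                                  min_separation = 5L,
                                  condition = "optimal", seed = 1L) {
  assert_genes(genes)
  if (n_direct + n_indirect > nrow(genes)) {
    stop("n_direct + n_indirect exceeds the number of genes")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  clens <- setNames(Biostrings::width(genome), names(genome))
  prom <- promoter_windows(genes, upstream, contig_lengths = clens)
  wmin <- peak_width_range[1]
  wmax <- peak_width_range[2]

  # Regulated genes are chosen so their promoter windows are pairwise
  # disjoint: a site planted in one regulated promoter must not spill into
  # another regulated gene's window, or the planted direct/indirect split
  # would not be exactly recoverable. Direct targets additionally need a
  # window wide enough to hold a whole site.
  wide <- prom$end - prom$start >= wmin
  if (sum(wide) < n_direct) stop("too few genes with usable promoter windows")
  window_clash <- function(i, chosen) {
    any(prom$contig[chosen] == prom$contig[i] &
          prom$start[chosen] < prom$end[i] &
          prom$start[i] < prom$end[chosen])
  }
  pick_disjoint <- function(candidates, k, chosen, weights = NULL) {
    order_of <- if (is.null(weights)) sample(candidates) else
      candidates[sample.int(length(candidates), length(candidates),
                            prob = weights)]
    picked <- integer()
    for (i in order_of) {
      if (length(picked) == k) break
      if (!window_clash(i, c(chosen, picked))) picked <- c(picked, i)
    }
    if (length(picked) < k) {
      stop("could not select ", k,
           " regulated genes with disjoint promoter windows")
    }
    picked
  }
  direct_weights <- NULL
  if (prefer_at_promoters) {
    wide_idx <- which(wide)
    prom_at <- vapply(wide_idx, function(i) {
      s <- Biostrings::subseq(genome[[prom$contig[i]]], prom$start[i] + 1L,
                              prom$end[i])
      sum(Biostrings::letterFrequency(s, c("A", "T"))) /
        (prom$end[i] - prom$start[i])
    }, numeric(1))
    direct_weights <- exp(promoter_at_weight * prom_at)
  }
  reg_idx <- pick_disjoint(which(wide), n_direct, integer(), direct_weights)
  rest <- setdiff(seq_len(nrow(genes)), reg_idx)
  ind_idx <- if (n_indirect > 0) pick_disjoint(rest, n_indirect, reg_idx)
             else integer()
  direct_ids <- genes$gene_id[reg_idx]
  indirect_ids <- genes$gene_id[ind_idx]

  # registry of placed sites; all sites stay >= min_separation bp apart
  pl_ctg <- character(); pl_s <- integer(); pl_e <- integer()
  site_clash <- function(ctg, s, e) {
    any(pl_ctg == ctg & s - min_separation < pl_e &
          pl_s < e + min_separation)
  }
  add_site <- function(ctg, s, e) {
    pl_ctg[[length(pl_ctg) + 1L]] <<- ctg
    pl_s[[length(pl_s) + 1L]] <<- s
    pl_e[[length(pl_e) + 1L]] <<- e
  }

  peaks_list <- list()
  classes <- character()
  for (i in reg_idx) {
    wlen <- prom$end[i] - prom$start[i]
    placed_one <- FALSE
    for (try in seq_len(200L)) {
      w <- min(wmax, wlen)
      w <- if (w > wmin) sample(wmin:w, 1L) else wmin
      s <- prom$start[i] + sample.int(wlen - w + 1L, 1L) - 1L
      if (site_clash(prom$contig[i], s, s + w)) next
      add_site(prom$contig[i], s, s + w)
      peaks_list[[length(peaks_list) + 1L]] <-
        data.frame(contig = prom$contig[i], start = s, end = s + w,
                   stringsAsFactors = FALSE)
      classes <- c(classes, "promoter_planted")
      placed_one <- TRUE
      break
    }
    if (!placed_one) {
      stop("could not place a promoter site for gene ", genes$gene_id[i])
    }
  }

  # promoter windows of every regulated gene are off limits for background
  forbidden <- prom[c(reg_idx, ind_idx), , drop = FALSE]

  touches_forbidden <- function(ctg, s, e) {
    any(forbidden$contig == ctg & s < forbidden$end & forbidden$start < e)
  }

  n_intra <- round(frac_intragenic * n_background)
  n_inter <- n_background - n_intra
  fits <- genes$end - genes$start >= wmax + 2L
  placed <- 0L
  tries <- 0L
  while (placed < n_intra) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, n_intra)) {
      stop("could not place intragenic background sites")
    }
    g <- sample(which(fits), 1L, prob = (genes$end - genes$start)[fits])
    w <- sample(wmin:wmax, 1L)
    s <- genes$start[g] + sample.int(genes$end[g] - genes$start[g] - w, 1L)
    # a neighbouring regulated gene's promoter window can reach into this
    # gene body, so the forbidden check applies here too
    if (touches_forbidden(genes$contig[g], s, s + w) ||
        site_clash(genes$contig[g], s, s + w)) next
    add_site(genes$contig[g], s, s + w)
    peaks_list[[length(peaks_list) + 1L]] <-
      data.frame(contig = genes$contig[g], start = s, end = s + w,
                 stringsAsFactors = FALSE)
    classes <- c(classes, "intragenic_background")
    placed <- placed + 1L
  }

  # Intergenic background: enumerate feasible site slots over the free
  # intergenic space (gaps minus regulated promoter windows and already
  # placed sites), then draw n_inter slots weighted by the AT content of
  # their segment. Slot enumeration makes feasibility deterministic.
  gaps <- intergenic_gaps(genes, clens)
  segs <- do.call(rbind, lapply(unique(gaps$contig), function(ctg) {
    gi <- IRanges::IRanges(gaps$start[gaps$contig == ctg] + 1L,
                           gaps$end[gaps$contig == ctg])
    block <- forbidden[forbidden$contig == ctg & forbidden$end >
                         forbidden$start, , drop = FALSE]
    used <- which(pl_ctg == ctg)
    bi <- IRanges::IRanges(
      start = c(block$start + 1L, pl_s[used] - min_separation + 1L),
      end = c(block$end, pl_e[used] + min_separation))
    free <- BiocGenerics::setdiff(gi, IRanges::reduce(bi))
    if (length(free) == 0) return(NULL)
    data.frame(contig = ctg, start = BiocGenerics::start(free) - 1L,
               end = BiocGenerics::end(free), stringsAsFactors = FALSE)
  }))
  if (is.null(segs)) {
    segs <- data.frame(contig = character(), start = integer(),
                       end = integer())
  }
  segs <- segs[segs$end - segs$start >= wmin, , drop = FALSE]
  slots <- list()
  for (i in seq_len(nrow(segs))) {
    at <- {
      ss <- Biostrings::subseq(genome[[segs$contig[i]]], segs$start[i] + 1L,
                               segs$end[i])
      sum(Biostrings::letterFrequency(ss, c("A", "T"))) /
        (segs$end[i] - segs$start[i])
    }
    pos <- segs$start[i] + sample.int(min_separation + 1L, 1L) - 1L
    while (pos + wmin <= segs$end[i]) {
      w <- sample(wmin:min(wmax, segs$end[i] - pos), 1L)
      slots[[length(slots) + 1L]] <- data.frame(
        contig = segs$contig[i], start = pos, end = pos + w, at = at,
        stringsAsFactors = FALSE)
      pos <- pos + w + min_separation
    }
  }
  if (length(slots) < n_inter) {
    stop("could not place background sites outside regulated promoters (",
         length(slots), " feasible slots for ", n_inter, " sites)")
  }
  slots <- do.call(rbind, slots)
  pick <- sample.int(nrow(slots), n_inter, prob = exp(at_weight * slots$at))
  for (j in pick) {
    add_site(slots$contig[j], slots$start[j], slots$end[j])
    peaks_list[[length(peaks_list) + 1L]] <-
      data.frame(contig = slots$contig[j], start = slots$start[j],
                 end = slots$end[j], stringsAsFactors = FALSE)
    classes <- c(classes, "intergenic_background")
  }

  peaks <- do.call(rbind, c(peaks_list, list(make.row.names = FALSE)))
  peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  peaks$midpoint <- (peaks$start + peaks$end) %/% 2L
  peaks$score <- NA_real_
  peaks <- peaks[, c("peak_id", "contig", "start", "end", "midpoint", "score")]
  peak_classes <- data.frame(peak_id = peaks$peak_id, class = classes,
                             stringsAsFactors = FALSE)

  # DE table over every gene
  n <- nrow(genes)
  log2fc <- pmax(pmin(rnorm(n, 0, 0.4), 1.5), -1.5) # noise stays subthreshold
  adj_p <- runif(n)
  reg_all <- c(reg_idx, ind_idx)
  sgn <- ifelse(runif(length(reg_all)) < prop_repressed, 1, -1)
  log2fc[reg_all] <- sgn * (lfc_threshold + 0.1 + rgamma(length(reg_all),
                                                         shape = 2, rate = 2))
  adj_p[reg_all] <- 10^-runif(length(reg_all), 4, 10)
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, adj_p = adj_p,
                   condition = condition, stringsAsFactors = FALSE)

  list(peaks = peaks, de = de,
       truth = list(direct_targets = sort(direct_ids),
                    indirect_targets = sort(indirect_ids),
                    peak_classes = peak_classes,
                    lfc_threshold = lfc_threshold,
                    condition = condition, seed = seed))
}

# Complement of the gene intervals on each contig (0-based half-open).
intergenic_gaps <- function(genes, contig_lengths) {
  rows <- lapply(names(contig_lengths), function(ctg) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds_start <- c(0L, g$end)
    bounds_end <- c(g$start, contig_lengths[[ctg]])
    keep <- bounds_end > bounds_start
    data.frame(contig = ctg, start = bounds_start[keep],
               end = bounds_end[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate AFM roughness line profiles for two strains
#'
#' Each cell gets a target Ra drawn from its group's normal distribution
#' (defaults: wild type 4.68 +/- 1.25 nm, deletion mutant 3.33 +/- 1.81 nm,
#' 50 cells per group) and 3 or 4 scan lines of Gaussian heights with
#' sigma = Ra / sqrt(2/pi), the noise level whose expected arithmetic mean
#' deviation equals the target Ra.
#'
#' @param n_cells_per_group cells per group.
#' @param group_params named list of c(mean, sd) target-Ra parameters (nm).
#' @param lines_per_cell candidate line counts, sampled per cell.
#' @param samples_per_line height samples along each 500-nm line.
#' @param min_ra floor for drawn target Ra (redraws below it).
#' @param seed RNG seed.
#' @return list(profiles = data.frame(group, cell_id, line_id, sample_index,
#'   height_nm), truth = list(group_params, n_cells_per_group, seed)).
#' @export
simulate_roughness <- function(n_cells_per_group = 50L,
                               group_params = list(
                                 wild_type = c(mean = 4.68, sd = 1.25),
                                 mutant = c(mean = 3.33, sd = 1.81)),
                               lines_per_cell = c(3L, 4L),
                               samples_per_line = 256L, min_ra = 0.2,
                               seed = 1L) {
  stopifnot(all(vapply(group_params, function(p) p[["sd"]] > 0, logical(1))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (grp in names(group_params)) {
    p <- group_params[[grp]]
    for (ci in seq_len(n_cells_per_group)) {
      target <- rnorm(1, p[["mean"]], p[["sd"]])
      while (target < min_ra) target <- rnorm(1, p[["mean"]], p[["sd"]])
      sigma <- target / sqrt(2 / pi)
      nl <- if (length(lines_per_cell) > 1) sample(lines_per_cell, 1L)
            else lines_per_cell
      for (li in seq_len(nl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp,
          cell_id = sprintf("%s_cell_%03d", grp, ci),
          line_id = sprintf("line_%d", li),
          sample_index = seq_len(samples_per_line),
          height_nm = rnorm(samples_per_line, 0, sigma),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  profiles <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(profiles = profiles,
       truth = list(group_params = group_params,
                    n_cells_per_group = n_cells_per_group, seed = seed))
}

#' Simulate a complete desk-scale dataset
#'
#' Fans a master seed out to fixed per-component child seeds (genome,
#' annotation, peaks/DE, roughness), so regenerating one component never
#' shifts the others, and optionally writes every input file plus the truth
#' tables and a run manifest to `dir`.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed); NULL to skip writing.
#' @param contig_len,n_genes,n_direct,n_background headline scale parameters
#'   (passed through to the component generators).
#' @param ... further arguments passed to [simulate_peaks_and_de()].
#' @return list(genome, islands, genes, peaks, de, roughness_profiles, truth,
#'   files).
#' @export
simulate_dataset <- function(seed = 1L, dir = NULL, contig_len = 200000L,
                             n_genes = 200L, n_direct = 30L,
                             n_background = 150L, ...) {
  gsim <- simulate_genome(contig_len = contig_len,
                          seed = derive_seed(seed, "genome"))
  genes <- simulate_annotation(gsim$genome, n_genes = n_genes,
                               islands = gsim$islands,
                               seed = derive_seed(seed, "annotation"))
  pd <- simulate_peaks_and_de(gsim$genome, genes, n_direct = n_direct,
                              n_background = n_background,
                              seed = derive_seed(seed, "peaks"), ...)
  rough <- simulate_roughness(seed = derive_seed(seed, "roughness"))
  truth <- c(list(islands = gsim$islands, master_seed = seed), pd$truth,
             roughness = list(rough$truth))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome = write_fasta(gsim$genome, file.path(dir, "genome.fasta")),
      genes = write_gff3(genes, file.path(dir, "genes.gff3")),
      peaks = write_bed(pd$peaks, file.path(dir, "peaks.bed")),
      de = file.path(dir, "de_table.tsv"),
      roughness = file.path(dir, "roughness.tsv"),
      truth_peaks = file.path(dir, "truth_peak_classes.tsv"),
      truth_islands = file.path(dir, "truth_islands.tsv"),
      truth_targets = file.path(dir, "truth_targets.tsv"),
      manifest = file.path(dir, "manifest.txt")
    )
    write_de_table(pd$de, files[["de"]])
    write.table(rough$profiles, files[["roughness"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pd$truth$peak_classes, files[["truth_peaks"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gsim$islands, files[["truth_islands"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    targets <- rbind(
      data.frame(gene_id = pd$truth$direct_targets, class = "direct"),
      data.frame(gene_id = pd$truth$indirect_targets, class = "indirect")
    )
    write.table(targets, files[["truth_targets"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_manifest(list(master_seed = seed, contig_len = contig_len,
                        n_genes = n_genes, n_direct = n_direct,
                        n_background = n_background,
                        condition = pd$truth$condition,
                        lfc_threshold = pd$truth$lfc_threshold),
                   files[["manifest"]])
  }
  list(genome = gsim$genome, islands = gsim$islands, genes = genes,
       peaks = pd$peaks, de = pd$de, roughness_profiles = rough$profiles,
       truth = truth, files = files)
}

#' Simulate a promoter set with controlled AT composition
#'
#' Builds `n` upstream sequences of length `L` whose per-promoter AT
#' fractions are normally distributed around `mean_at` with SD `sd_at`: each
#' sequence carries exactly round(at_i * L) A/T bases at shuffled positions,
#' so the realized per-promoter fractions match the drawn ones to rounding.
#' Used to study the power of the promoter-composition test at a known
#' effect size.
#'
#' @param n number of promoters.
#' @param L sequence length in bp.
#' @param mean_at,sd_at mean and SD of per-promoter AT fraction.
#' @param seed RNG seed.
#' @param label set label.
#' @return a `promoter_set` object.
#' @export
simulate_promoter_set <- function(n = 50L, L = 150L, mean_at = 0.36,
                                  sd_at = 0.04, seed = 1L,
                                  label = "synthetic") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  at_i <- pmin(pmax(rnorm(n, mean_at, sd_at), 0), 1)
  seqs <- vapply(at_i, function(a) {
    k <- round(a * L)
    bases <- c(sample(c("A", "T"), k, replace = TRUE),
               sample(c("C", "G"), L - k, replace = TRUE))
    paste(sample(bases), collapse = "")
  }, character(1))
  structure(list(label = label, upstream = as.integer(L),
                 members = data.frame(gene_id = sprintf("prom_%04d", seq_len(n)),
                                      sequence = seqs,
                                      stringsAsFactors = FALSE)),
            class = "promoter_set")
}
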