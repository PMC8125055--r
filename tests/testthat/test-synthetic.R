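test_that("genome simulation is deterministic and composition-faithful", {
  a <- simulate_genome(contig_len = 5000L, n_islands = 2L, island_len = 500L,
                       seed = 42L)
  b <- simulate_genome(contig_len = 5000L, n_islands = 2L, island_len = 500L,
                       seed = 42L)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$islands, b$islands)

  # zero islands: whole-genome AT within 3 binomial SDs of 1 - baseline_gc
  no_isl <- simulate_genome(contig_len = 50000L, n_islands = 0L,
                            baseline_gc = 0.67, seed = 17L)
  f <- Biostrings::letterFrequency(no_isl$genome, c("A", "T"))
  at <- sum(f) / 50000
  expect_lt(abs(at - 0.33), 3 * sqrt(0.33 * 0.67 / 50000))

  expect_error(simulate_genome(island_at = 0.2), "island_at")
})

test_that("extreme islands are recovered exactly at window resolution", {
  sim <- simulate_genome(contig_len = 30000L, n_islands = 3L,
                         island_len = 2000L, island_at = 1.0, seed = 19L)
  w <- compute_at_windows(sim$genome, 500, 500)
  regions <- at_rich_regions(w, threshold = 0.999)
  expect_equal(nrow(regions), 3L)
  for (i in 1:3) {
    # every fully-AT region sits inside an island, within window resolution
    j <- which(regions$start >= sim$islands$start[i] - 500 &
                 regions$end <= sim$islands$end[i] + 500)
    expect_length(j, 1)
  }
})

test_that("annotation simulation packs genes with positive gaps", {
  genome <- random_genome(250000L, seed = 23L)
  genes <- simulate_annotation(genome, n_genes = 220L, seed = 23L)
  expect_equal(nrow(genes), 220L)
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)])) # positive gaps
  mean_len <- mean(genes$end - genes$start)
  expect_lt(abs(mean_len - 946) / 946, 0.05)

  small <- random_genome(10000L, seed = 24L)
  expect_error(simulate_annotation(small, n_genes = 20L,
                                   mean_gene_len = 946L, sd_gene_len = 1L),
               "fit")
})

test_that("an all-plus annotation forces tandem intergenic classification", {
  genome <- random_genome(60000L, seed = 25L)
  genes <- simulate_annotation(genome, n_genes = 50L, strand_mix = 1,
                               seed = 25L)
  gaps <- data.frame(start = head(genes$end, -1), end = genes$start[-1])
  gaps <- gaps[gaps$end - gaps$start >= 3, ]
  mids <- as.integer((gaps$start + gaps$end) / 2)
  ctx <- classify_peaks(peaks_at_midpoints(mids, halfwidth = 1L), genes)
  expect_true(all(ctx$category == "intergenic_tandem"))
})

test_that("peak/DE simulation honours its planted structure", {
  sim <- default_sim()
  truth <- sim$truth

  # every direct target has a site wholly inside its promoter window
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  prom <- promoter_windows(sim$genes, 150, lens)
  planted <- sim$peaks[truth$peak_classes$class == "promoter_planted", ]
  for (i in seq_along(truth$direct_targets)) {
    w <- prom[prom$gene_id == truth$direct_targets[i], ]
    inside <- any(planted$start >= w$start & planted$end <= w$end)
    expect_true(inside, label = paste("promoter site for",
                                      truth$direct_targets[i]))
  }

  # no background site touches a regulated gene's promoter window
  reg_prom <- prom[prom$gene_id %in% c(truth$direct_targets,
                                       truth$indirect_targets), ]
  background <- sim$peaks[truth$peak_classes$class != "promoter_planted", ]
  touches <- outer(seq_len(nrow(background)), seq_len(nrow(reg_prom)),
                   Vectorize(function(i, j) {
                     background$start[i] < reg_prom$end[j] &
                       reg_prom$start[j] < background$end[i]
                   }))
  expect_false(any(touches))

  # noise genes stay below the regulon thresholds
  noise <- !sim$de$gene_id %in% c(truth$direct_targets, truth$indirect_targets)
  expect_true(all(abs(sim$de$log2fc[noise]) <= 1.5))
  expect_true(all(abs(sim$de$log2fc[!noise]) > 1.585))

  # background sites are AT-enriched relative to the genome
  w500 <- compute_at_windows(sim$genome, 500, 500)
  win_of <- function(mid) w500$at_fraction[mid %/% 500 + 1]
  inter <- background[truth$peak_classes$class[
    match(background$peak_id, truth$peak_classes$peak_id)] ==
      "intergenic_background", ]
  expect_gt(mean(vapply(inter$midpoint, win_of, numeric(1)), na.rm = TRUE),
            mean(w500$at_fraction, na.rm = TRUE))
})

test_that("n_direct = 0 yields a regulon with no direct targets", {
  genome <- random_genome(50000L, seed = 26L, at = 0.33)
  genes <- simulate_annotation(genome, n_genes = 40L, seed = 26L)
  pd <- simulate_peaks_and_de(genome, genes, n_direct = 0L, n_indirect = 5L,
                              n_background = 30L, seed = 26L)
  reg <- call_regulon(pd$de, "optimal")
  reg <- assign_direct_targets(reg, pd$peaks, genes, 150,
                               c(contig_01 = 50000L, c1 = 50000L))
  expect_equal(sum(reg$entries$mode == "direct"), 0L)
  expect_setequal(reg$entries$gene_id, pd$truth$indirect_targets)
})

test_that("generators restore the caller's RNG stream", {
  set.seed(555)
  before <- runif(3)
  set.seed(555)
  invisible(simulate_genome(contig_len = 2000L, n_islands = 0L, seed = 1L))
  invisible(simulate_roughness(n_cells_per_group = 2, samples_per_line = 8,
                               seed = 1L))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("the master seed fans out to reproducible components", {
  d1 <- withr::local_tempdir()
  sim1 <- simulate_dataset(seed = 99L, dir = d1, contig_len = 60000L,
                           n_genes = 60L, n_direct = 8L, n_background = 40L)
  d2 <- withr::local_tempdir()
  sim2 <- simulate_dataset(seed = 99L, dir = d2, contig_len = 60000L,
                           n_genes = 60L, n_direct = 8L, n_background = 40L)
  for (f in c("genome.fasta", "genes.gff3", "peaks.bed", "de_table.tsv",
              "roughness.tsv", "truth_targets.tsv", "manifest.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste(f, "bytes"))
  }
  expect_identical(sim1$truth$direct_targets, sim2$truth$direct_targets)
})
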