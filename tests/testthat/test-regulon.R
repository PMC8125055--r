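test_that("regulon calling applies the strict fold-change rule", {
  de <- make_de(sprintf("g%02d", 1:4),
                log2fc = c(1.585, 1.586, -2.0, 0.3),
                adj_p = c(0.01, 0.01, 0.01, 0.01))
  reg <- call_regulon(de, "optimal")
  expect_setequal(reg$entries$gene_id, c("g02", "g03")) # 1.585 itself excluded
  expect_equal(reg$entries$direction[reg$entries$gene_id == "g02"],
               "repressed_by_nap")
  expect_equal(reg$entries$direction[reg$entries$gene_id == "g03"],
               "activated_by_nap")
  expect_error(call_regulon(de, "hypoxia"), "no DE records")
})

test_that("the p-value filter is applied and can be disabled", {
  de <- make_de(c("g1", "g2"), log2fc = c(3, 3), adj_p = c(0.2, 0.01))
  expect_equal(call_regulon(de, "optimal")$entries$gene_id, "g2")
  expect_setequal(call_regulon(de, "optimal", p_threshold = NULL)$entries$gene_id,
                  c("g1", "g2"))
})

test_that("regulon membership equals a brute-force filter and is monotone", {
  set.seed(61)
  de <- make_de(sprintf("g%03d", 1:200), log2fc = rnorm(200, 0, 1.5),
                adj_p = runif(200))
  reg <- call_regulon(de, "optimal", lfc_threshold = 1.2, p_threshold = 0.1)
  brute <- de$gene_id[abs(de$log2fc) > 1.2 & de$adj_p <= 0.1]
  expect_setequal(reg$entries$gene_id, brute)

  sizes <- vapply(seq(0.5, 3, by = 0.25), function(th)
    nrow(call_regulon(de, "optimal", lfc_threshold = th)$entries), integer(1))
  expect_true(all(diff(sizes) <= 0)) # raising the threshold never adds genes
})

test_that("fold-to-threshold conversion is exact", {
  expect_equal(lfc_threshold_for_fold(3), 1.585)
  expect_equal(lfc_threshold_for_fold(1), 0)
  expect_equal(lfc_threshold_for_fold(2^c(1, 3, 5)), c(1, 3, 5))
  expect_error(lfc_threshold_for_fold(0), "fold")
})

test_that("promoter windows are strand-aware and clipped", {
  genes <- make_genes(starts = c(1000, 2000, 50), ends = c(1500, 2400, 600),
                      strands = c("+", "-", "+"))
  w <- promoter_windows(genes, 150)
  expect_equal(c(w$start[1], w$end[1]), c(850L, 1000L))
  expect_equal(c(w$start[2], w$end[2]), c(2400L, 2550L))
  expect_equal(c(w$start[3], w$end[3]), c(0L, 50L)) # clipped at the origin

  clipped <- promoter_windows(make_genes(900, 950, "-"), 150,
                              contig_lengths = c(c1 = 1000L))
  expect_equal(clipped$end, 1000L)

  # batch equals an independent strand-aware computation
  genome <- random_genome(30000L, seed = 71L)
  ann <- simulate_annotation(genome, n_genes = 25L, seed = 71L)
  w2 <- promoter_windows(ann, 150, contig_lengths = c(c1 = 30000L))
  for (i in seq_len(nrow(ann))) {
    expected <- if (ann$strand[i] == "+") {
      c(max(0, ann$start[i] - 150), ann$start[i])
    } else {
      c(ann$end[i], min(30000, ann$end[i] + 150))
    }
    expect_equal(c(w2$start[i], w2$end[i]), as.integer(expected))
  }
})

test_that("direct-target assignment uses half-open any-overlap", {
  genes <- make_genes(1000, 1500, "+") # promoter window [850, 1000)
  de <- make_de("g01", log2fc = 2.5)
  reg <- call_regulon(de, "optimal")

  touching <- make_peaks(800, 850) # ends exactly at window start: no overlap
  r1 <- assign_direct_targets(reg, touching, genes)
  expect_equal(r1$entries$mode, "indirect")
  expect_equal(r1$entries$supporting_peaks, "")

  one_bp <- make_peaks(800, 851) # covers 1 bp of the window
  r2 <- assign_direct_targets(reg, one_bp, genes)
  expect_equal(r2$entries$mode, "direct")
  expect_equal(r2$entries$supporting_peaks, "p01")

  expect_error(assign_direct_targets(reg, one_bp,
                                     make_genes(1, 2, "+", ids = "other")),
               "g01")
})

test_that("assignment fills modes without changing membership", {
  sim <- default_sim()
  reg <- call_regulon(sim$de, "optimal")
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  reg2 <- assign_direct_targets(reg, sim$peaks, sim$genes, 150, lens)
  expect_equal(reg2$entries$gene_id, reg$entries$gene_id)
  # planted direct targets are recovered with precision = recall = 1
  called <- sort(reg2$entries$gene_id[reg2$entries$mode == "direct"])
  expect_identical(called, sim$truth$direct_targets)
  expect_identical(sort(reg2$entries$gene_id[reg2$entries$mode == "indirect"]),
                   sim$truth$indirect_targets)
  # mode = direct iff supporting peaks present
  expect_equal(reg2$entries$mode == "direct",
               reg2$entries$supporting_peaks != "")
})

test_that("regulon summaries reproduce the printed percentages", {
  mk <- function(n, n_act, condition = "x") {
    de <- make_de(sprintf("g%03d", 1:n),
                  log2fc = c(rep(-2, n_act), rep(2, n - n_act)),
                  condition = condition)
    call_regulon(de, condition)
  }
  optimal <- mk(71, 71 - 59)
  s <- regulon_summary(optimal)
  expect_equal(s$n_repressed, 59L)
  expect_equal(s$pct_with_decreased_transcription_in_mutant, 17)

  hypoxia <- mk(124, 57)
  expect_equal(regulon_summary(hypoxia)$pct_activated, 46)

  empty <- mk(3, 0)
  empty$entries <- empty$entries[0, ]
  s0 <- regulon_summary(empty)
  expect_true(all(unlist(s0) == 0))

  set.seed(9)
  rnd <- call_regulon(make_de(sprintf("g%02d", 1:30),
                              log2fc = sample(c(-3, 3), 30, TRUE)), "optimal")
  sr <- regulon_summary(rnd)
  expect_equal(sr$n_repressed + sr$n_activated, sr$n_total)
  expect_lte(sr$n_direct, sr$n_total)
})

test_that("regulon comparison is exact set arithmetic", {
  mk <- function(ids, condition) {
    call_regulon(make_de(ids, log2fc = 2, condition = condition), condition)
  }
  a <- mk(sprintf("s%03d", 1:71), "optimal") # 36 shared + 35 unique
  b <- mk(sprintf("%s%03d", c(rep("s", 36), rep("h", 88)),
                  c(1:36, 1:88)), "hypoxia")
  cmp <- compare_regulons(a, b)
  expect_equal(c(cmp$n_shared, cmp$n_unique_a, cmp$n_unique_b),
               c(36L, 35L, 88L))
  expect_equal(cmp$n_shared + cmp$n_unique_a, 71L)
  expect_equal(cmp$n_shared + cmp$n_unique_b, 124L)

  same <- compare_regulons(a, a)
  expect_equal(same$n_shared, 71L)
  expect_equal(same$n_unique_a + same$n_unique_b, 0L)

  disjoint <- compare_regulons(mk(c("x1", "x2"), "a"), mk(c("y1"), "b"))
  expect_equal(disjoint$n_shared, 0L)
})
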