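test_that("peak classification follows the orientation truth table", {
  genes <- make_genes(starts = c(100, 500), ends = c(300, 700),
                      strands = c("+", "+"))
  mid <- peaks_at_midpoints(400)
  expect_equal(classify_peaks(mid, genes)$category, "intergenic_tandem")

  genes$strand <- c("+", "-") # 3' ends face the peak
  expect_equal(classify_peaks(mid, genes)$category, "intergenic_convergent")

  genes$strand <- c("-", "+") # 5' ends face the peak
  expect_equal(classify_peaks(mid, genes)$category, "intergenic_divergent")

  inside <- peaks_at_midpoints(200)
  ctx <- classify_peaks(inside, genes)
  expect_equal(ctx$category, "intragenic")
  expect_equal(ctx$left_gene_id, "g01")

  ends <- peaks_at_midpoints(c(50, 900))
  expect_equal(classify_peaks(ends, genes)$category, rep("terminal", 2))

  expect_error(classify_peaks(peaks_at_midpoints(10, contig = "c9"), genes),
               "c9")
})

test_that("classification matches a brute-force oracle on random peaks", {
  genome <- random_genome(20000L, seed = 31L)
  genes <- simulate_annotation(genome, n_genes = 18L, mean_gene_len = 700L,
                               sd_gene_len = 200L, seed = 31L)
  set.seed(99)
  peaks <- peaks_at_midpoints(sample.int(19990L, 200L) + 2L)
  got <- classify_peaks(peaks, genes)
  expect_equal(got$category, brute_classify(peaks, genes))
  # categories are exhaustive
  expect_false(anyNA(got$category))
})

test_that("architecture fractions reproduce simple arithmetic", {
  ctx <- data.frame(peak_id = sprintf("p%02d", 1:50),
                    category = c(rep("intergenic_tandem", 43),
                                 rep("intragenic", 7)))
  tab <- architecture_fractions(ctx)
  expect_equal(tab$percentage[tab$category == "intergenic"], 86)
  expect_equal(sum(tab$count[tab$category != "intergenic"]), 50L)

  all_intra <- data.frame(peak_id = "p1", category = "intragenic")
  t2 <- architecture_fractions(all_intra)
  expect_equal(t2$percentage[t2$category == "intragenic"], 100)
})

test_that("a planted intergenic/intragenic split is recovered", {
  genome <- random_genome(100000L, seed = 41L)
  genes <- simulate_annotation(genome, n_genes = 80L, mean_gene_len = 900L,
                               seed = 41L)
  set.seed(41)
  # 400 midpoints in internal intergenic gaps, 100 inside gene bodies
  gaps <- data.frame(start = head(genes$end, -1), end = genes$start[-1])
  gaps <- gaps[gaps$end - gaps$start >= 3, , drop = FALSE]
  gap_pick <- gaps[sample.int(nrow(gaps), 400L, replace = TRUE), ]
  inter_mid <- mapply(function(s, e) sample(seq.int(s, e - 1L), 1L),
                      gap_pick$start, gap_pick$end)
  gene_pick <- genes[sample.int(nrow(genes), 100L, replace = TRUE), ]
  intra_mid <- mapply(function(s, e) sample(seq.int(s, e - 1L), 1L),
                      gene_pick$start, gene_pick$end)
  peaks <- peaks_at_midpoints(c(inter_mid, intra_mid), halfwidth = 0L)
  peaks$end <- peaks$start + 1L
  peaks$midpoint <- peaks$start
  tab <- architecture_fractions(classify_peaks(peaks, genes))
  expect_lt(abs(tab$percentage[tab$category == "intergenic"] - 80), 4 + 1e-9)
  expect_lt(abs(tab$percentage[tab$category == "intragenic"] - 20), 4 + 1e-9)
})

test_that("nearest-neighbour distances match hand and brute-force values", {
  p <- peaks_at_midpoints(c(0, 100, 300) + 5L)
  expect_equal(sort(nearest_peak_distances(p)), c(100L, 100L, 200L))

  two <- peaks_at_midpoints(c(10, 500))
  expect_equal(nearest_peak_distances(two), c(490L, 490L))

  set.seed(77)
  mids <- sample.int(1e6, 100L)
  many <- peaks_at_midpoints(mids)
  brute <- vapply(seq_along(mids), function(i)
    min(abs(mids[-i] - mids[i])), numeric(1))
  expect_equal(sort(nearest_peak_distances(many)), sort(as.integer(brute)))

  expect_error(nearest_peak_distances(peaks_at_midpoints(10)), "at least two")
})

test_that("spacing is invariant under relabeling and translation", {
  set.seed(12)
  mids <- sort(sample.int(50000L, 40L))
  p <- peaks_at_midpoints(mids)
  shuffled <- p[sample.int(nrow(p)), ]
  shuffled$peak_id <- rev(shuffled$peak_id)
  expect_equal(sort(nearest_peak_distances(p)),
               sort(nearest_peak_distances(shuffled)))
  moved <- peaks_at_midpoints(mids + 1234L)
  expect_equal(sort(nearest_peak_distances(p)),
               sort(nearest_peak_distances(moved)))
})

test_that("quartiles follow the hinge and interpolation definitions", {
  expect_equal(spacing_quartiles(1:5, "hinges"),
               c(q1 = 2, median = 3, q3 = 4))
  expect_equal(spacing_quartiles(1:5, "linear"),
               c(q1 = 1.5, median = 3, q3 = 4.5))
  expect_equal(spacing_quartiles(rep(7, 10)), c(q1 = 7, median = 7, q3 = 7))

  # oracle: split-halves hinge computation on sorted values
  set.seed(5)
  x <- rnorm(1000)
  xs <- sort(x)
  n <- length(xs)
  lower <- xs[1:ceiling(n / 2)]
  upper <- xs[floor(n / 2 + 1):n]
  expect_equal(spacing_quartiles(x, "hinges"),
               c(q1 = median(lower), median = median(xs), q3 = median(upper)))
  # oracle: textbook (n+1)p interpolation for the linear method
  lin <- vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n + 1) * p
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }, numeric(1))
  expect_equal(unname(spacing_quartiles(x, "linear")), lin, tolerance = 1e-12)
})

test_that("the bridged-gene estimate divides the IQR by the gene length", {
  expect_equal(bridged_gene_range(1933, 15390, 946),
               c(min_genes = 2L, max_genes = 16L))
  expect_equal(bridged_gene_range(500, 945, 946),
               c(min_genes = 0L, max_genes = 0L))
  expect_error(bridged_gene_range(0, 100), "q1")
  expect_error(bridged_gene_range(10, 100, 0), "avg_gene_len")

  set.seed(3)
  for (i in 1:50) {
    q <- sort(runif(2, 1, 50000))
    len <- runif(1, 100, 2000)
    got <- bridged_gene_range(q[1], q[2], len)
    expect_equal(unname(got),
                 c(as.integer(floor(q[1] / len)),
                   as.integer(floor(q[2] / len))))
  }
  # monotone in q1/q3, non-increasing in gene length
  expect_true(bridged_gene_range(2000, 16000)[2] >=
                bridged_gene_range(2000, 15000)[2])
  expect_true(bridged_gene_range(2000, 15000, 500)[2] >=
                bridged_gene_range(2000, 15000, 1000)[2])
})
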