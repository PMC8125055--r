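# Shared in-code fixtures and small constructors. Everything is generated at
# test time; nothing is read from disk except files the tests write.

make_genes <- function(starts, ends, strands, contig = "c1",
                       ids = sprintf("g%02d", seq_along(starts))) {
  data.frame(gene_id = ids, contig = contig, start = as.integer(starts),
             end = as.integer(ends), strand = strands,
             stringsAsFactors = FALSE)
}

make_peaks <- function(starts, ends, contig = "c1",
                       ids = sprintf("p%02d", seq_along(starts))) {
  data.frame(peak_id = ids, contig = contig, start = as.integer(starts),
             end = as.integer(ends),
             midpoint = (as.integer(starts) + as.integer(ends)) %/% 2L,
             score = NA_real_, stringsAsFactors = FALSE)
}

peaks_at_midpoints <- function(midpoints, contig = "c1", halfwidth = 1L) {
  make_peaks(midpoints - halfwidth, midpoints + halfwidth, contig = contig)
}

make_de <- function(gene_id, log2fc, adj_p = 1e-4, condition = "optimal") {
  data.frame(gene_id = gene_id, log2fc = log2fc, adj_p = adj_p,
             condition = condition, stringsAsFactors = FALSE)
}

random_genome <- function(len, seed, at = 0.5, name = "c1") {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "T", "C", "G"), len, replace = TRUE,
           prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
    collapse = ""))
  names(g) <- name
  g
}

# The default-scale synthetic dataset is used by several test files; build it
# once per session.
.fixture_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 11L) {
  key <- paste0("sim_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_dataset(seed = seed)
  }
  .fixture_cache[[key]]
}

# Independent brute-force classifier used as the oracle: scans every gene.
brute_classify <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks$midpoint[i]
    g <- genes[genes$contig == peaks$contig[i], , drop = FALSE]
    inside <- g[g$start <= p & p < g$end, , drop = FALSE]
    if (nrow(inside)) return("intragenic")
    left <- g[g$end <= p, , drop = FALSE]
    right <- g[g$start > p, , drop = FALSE]
    if (nrow(left) == 0 || nrow(right) == 0) return("terminal")
    l <- left[which.max(left$end), ]
    r <- right[which.min(right$start), ]
    if (l$strand == r$strand) return("intergenic_tandem")
    if (l$strand == "+") "intergenic_convergent" else "intergenic_divergent"
  }, character(1))
}

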