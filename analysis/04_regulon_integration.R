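#!/usr/bin/env Rscript
# Regulon calling and direct-target assignment: genes with |log2FC| >
# log2(3) = 1.585 and adj_p <= 0.05 form the regulon; a regulon gene is a
# direct target when a binding site overlaps the 150 bp upstream of its
# start codon. The called direct set is scored against the planted truth.
# A second, hypoxia-like condition is then simulated on the same genome and
# the two regulons are compared.

library(napregulon)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
genome <- read_fasta("results/synthetic_data/genome.fasta")
genes <- read_gff3("results/synthetic_data/genes.gff3")
peaks <- read_bed("results/synthetic_data/peaks.bed")
de <- read_de_table("results/synthetic_data/de_table.tsv",
                    condition = "optimal")
truth <- read.table("results/synthetic_data/truth_targets.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
lens <- setNames(Biostrings::width(genome), names(genome))

regulon <- call_regulon(de, "optimal")
regulon <- assign_direct_targets(regulon, peaks, genes, upstream = 150,
                                 contig_lengths = lens)
print(regulon)
write_regulon(regulon, "results/regulon_optimal.tsv")

called <- regulon$entries$gene_id[regulon$entries$mode == "direct"]
planted <- truth$gene_id[truth$class == "direct"]
cat("direct-target precision:",
    length(intersect(called, planted)) / length(called),
    " recall:", length(intersect(called, planted)) / length(planted), "\n")

# hypoxia-like condition: more targets, activation as common as repression
hyp <- simulate_peaks_and_de(genome, genes, n_direct = 40L, n_indirect = 35L,
                             n_background = 150L, prop_repressed = 0.55,
                             condition = "hypoxia", seed = seed + 50021L)
regulon_hyp <- call_regulon(hyp$de, "hypoxia")
regulon_hyp <- assign_direct_targets(regulon_hyp, hyp$peaks, genes,
                                     upstream = 150, contig_lengths = lens)
print(regulon_hyp)
write_regulon(regulon_hyp, "results/regulon_hypoxia.tsv")

cmp <- compare_regulons(regulon, regulon_hyp)
print(cmp)
write.table(
  data.frame(set = c("shared", "optimal_only", "hypoxia_only"),
             n = c(cmp$n_shared, cmp$n_unique_a, cmp$n_unique_b),
             genes = c(paste(cmp$shared, collapse = ";"),
                       paste(cmp$unique_a, collapse = ";"),
                       paste(cmp$unique_b, collapse = ";"))),
  "results/regulon_comparison.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
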