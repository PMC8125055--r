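#!/usr/bin/env Rscript
# Cell-surface roughness: per-cell Ra (arithmetic mean deviation of the
# height profile, averaged over the 3-4 scan lines per cell) for the two
# strains, compared with a two-sided pooled-SD t-test.

library(napregulon)

profiles <- read_roughness_tsv("results/synthetic_data/roughness.tsv")
profiles$group <- sub("_cell.*", "", profiles$cell_id)

per_cell <- cell_ra(profiles)
per_cell$group <- sub("_cell.*", "", per_cell$cell_id)
write.table(per_cell, "results/roughness_per_cell.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- compare_roughness_groups(per_cell[per_cell$group == "mutant", ],
                                per_cell[per_cell$group == "wild_type", ])
write.table(as.data.frame(cmp), "results/roughness_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("mutant:    Ra = %.2f +/- %.2f nm (n = %d cells)\n",
            cmp$mean_a, cmp$sd_a, cmp$n_a))
cat(sprintf("wild type: Ra = %.2f +/- %.2f nm (n = %d cells)\n",
            cmp$mean_b, cmp$sd_b, cmp$n_b))
cat(sprintf("pooled-SD t = %.2f (df = %d), two-sided p = %.3g\n",
            cmp$t_statistic, cmp$df, cmp$p_value))
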