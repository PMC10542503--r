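#!/usr/bin/env Rscript
# Stage 6: global expression structure. Sample Pearson correlation matrix
# (with average-linkage ordering) and PCA on per-locus-centered log2 CPM.

library(orthoDE)

counts <- read_count_matrix("results/data/counts.tsv")
samples <- read_sample_sheet("results/data/samples.tsv")
out <- "results/global"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

factors <- compute_tmm_factors(counts)
logcpm <- cpm_matrix(counts, factors, log2_transform = TRUE, pseudocount = 1)

cm <- sample_correlation_matrix(logcpm)
cat("sample ordering by expression similarity:\n")
cat(paste(cm$order, collapse = " "), "\n")

pc <- pca_expression(logcpm, n_components = 3)
cat(sprintf("PC variance fractions: %s\n",
            paste(sprintf("%.1f%%", 100 * pc$variance_fraction),
                  collapse = ", ")))
taxon <- samples$taxon[match(rownames(pc$scores), samples$sample)]
for (tx in unique(taxon))
  cat(sprintf("PC1 mean for %s: %8.2f\n", tx,
              mean(pc$scores[taxon == tx, 1])))

write.table(data.frame(sample = rownames(cm$cor), round(cm$cor, 4)),
            file.path(out, "sample_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = rownames(pc$scores), taxon = taxon,
                       round(pc$scores, 4)),
            file.path(out, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
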