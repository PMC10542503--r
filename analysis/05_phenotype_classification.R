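#!/usr/bin/env Rscript
# Stage 5: expression-phenotype classification over the six pairwise
# comparisons: parental DE (A), novel/transgressive expression in the
# hybrids (B), parent-like inheritance (C), and hybrid-hybrid DE (D),
# with the combined parent-bias summaries.

library(orthoDE)

counts <- read_count_matrix("results/data/counts.tsv")
samples <- read_sample_sheet("results/data/samples.tsv")
out <- "results/phenotypes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rules <- phenotype_rules(parents = c("bro", "fru"), hybrids = c("sun", "lem"))
de <- lapply(rules$comparisons, function(nm)
  read.delim(file.path("results/de", paste0("de_", nm, ".tsv")),
             stringsAsFactors = FALSE))
names(de) <- rules$comparisons

factors <- compute_tmm_factors(counts)
cpm <- cpm_matrix(counts, factors)
gm <- vapply(unique(samples$taxon), function(tx)
  rowMeans(cpm[, samples$sample[samples$taxon == tx], drop = FALSE]),
  numeric(nrow(cpm)))

res <- classify_all(de, gm, rules)
cat("phenotype category counts:\n")
print(res$counts)
cat(sprintf("novel total (B rows): %d\n", novel_total(res$counts)))
for (h in c("sun", "lem")) {
  b <- parent_bias_summary(res$counts, h)
  cat(sprintf("%s: %d bro-like vs %d fru-like (%s)\n", h,
              b$n_first_like, b$n_second_like, b$ratio))
}

write.table(res$calls, file.path(out, "phenotype_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$counts, file.path(out, "phenotype_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
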