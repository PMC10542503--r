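#!/usr/bin/env Rscript
# Stage 1: generate the synthetic four-taxon RNA-seq experiment.
#
# Two parental taxa (bro, fru) and two hybrid taxa (sun, lem), six
# replicates each, NB counts with common dispersion 0.1. A configured
# fraction of loci carries each expression-phenotype class; 2% of null loci
# are converted to split-ortholog artifacts and 2% to DE-paralog pairs, and
# a BLAST-style hit table links the artifact partners (plus ordinary
# gene-family mutual best hits and one-directional background noise).

library(orthoDE)

seed <- 20230721L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_loci = 4000, seed = seed)
sim <- simulate_counts(cfg)
sim <- inject_split_orthologs(sim, 0.02)
sim <- inject_de_paralogs(sim, 0.02)
hits <- emit_hit_table(sim$truth, noise_hits = 2000, seed = seed + 1L,
                       ortholog_fraction = 0.3)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_sample_sheet(sim$samples, file.path(out, "samples.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_hit_table(hits, file.path(out, "hits.tsv"))

n_split <- sum(sim$truth$artifact == "split_ortholog") / 2
n_par <- sum(sim$truth$artifact == "de_paralog") / 2
cat(sprintf("simulated %d transcripts x %d samples\n",
            nrow(sim$counts), ncol(sim$counts)))
cat(sprintf("truth classes: %s\n",
            paste(names(table(sim$truth$label)),
                  table(sim$truth$label), collapse = ", ")))
cat(sprintf("injected %d split-ortholog pairs and %d DE-paralog pairs; %d hits\n",
            n_split, n_par, nrow(hits)))
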