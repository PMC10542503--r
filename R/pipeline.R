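#' Analysis configuration
#'
#' Collects the tunables of an end-to-end run: the DE threshold, TMM trim
#' fractions, CPM pseudocount, k-mer length for the orthogroup filter, the
#' chi-squared null option, and the simulation settings (or input file
#' paths) feeding the run.
#'
#' @param n_loci loci to simulate when no count input is given.
#' @param seed RNG seed for the whole run.
#' @param alpha FDR threshold in (0, 1).
#' @param trim_m,trim_a TMM trim fractions in \[0, 0.5).
#' @param pseudocount CPM log2 pseudocount.
#' @param k k-mer length for orthogroup trees.
#' @param chi2_marginal `"members"` or `"external"` null for the RBBH test.
#' @param split_fraction,paralog_fraction artifact fractions for the
#'   simulation.
#' @param noise_hits background hits in the synthetic hit table.
#' @param ortholog_fraction fraction of ordinary transcripts emitted as
#'   mutual best pairs in the synthetic hit table.
#' @param n_ogs simulated orthogroups for the filter stage.
#' @param og_paralog_fraction fraction of contaminated orthogroups.
#' @param min_cpm optional low-expression CPM floor (NULL = keep all loci).
#' @param counts_file,samples_file optional TSV inputs replacing simulation.
#' @param out_dir optional output directory for stage TSVs and the manifest.
#' @param ... further fields stored verbatim (passed to [sim_config()]).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(n_loci = 2000, seed = 1, alpha = 0.05,
                            trim_m = 0.30, trim_a = 0.05, pseudocount = 1,
                            k = 6, chi2_marginal = "members",
                            split_fraction = 0.02, paralog_fraction = 0.02,
                            noise_hits = 1000, ortholog_fraction = 0.3,
                            n_ogs = 100,
                            og_paralog_fraction = 0.1, min_cpm = NULL,
                            counts_file = NULL, samples_file = NULL,
                            out_dir = NULL, ...) {
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must lie in (0, 1)")
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  structure(list(n_loci = n_loci, seed = as.integer(seed), alpha = alpha,
                 trim_m = trim_m, trim_a = trim_a, pseudocount = pseudocount,
                 k = k, chi2_marginal = chi2_marginal,
                 split_fraction = split_fraction,
                 paralog_fraction = paralog_fraction,
                 noise_hits = noise_hits,
                 ortholog_fraction = ortholog_fraction, n_ogs = n_ogs,
                 og_paralog_fraction = og_paralog_fraction,
                 min_cpm = min_cpm, counts_file = counts_file,
                 samples_file = samples_file, out_dir = out_dir,
                 extra = list(...)),
            class = "analysis_config")
}

#' Sample Pearson correlation matrix with a clustering order
#'
#' Pearson correlation over loci for every sample pair, with an average
#' linkage clustering on 1 - r supplying a display ordering. Zero-variance
#' samples yield undefined correlations and are flagged.
#'
#' @param logcpm numeric matrix, loci x samples (log2 CPM).
#' @return list with `cor` (symmetric, unit diagonal), `order` (sample ids
#'   in dendrogram order) and `undefined` (samples with zero variance).
#' @export
sample_correlation_matrix <- function(logcpm) {
  if (ncol(logcpm) < 2) stopf("need at least two samples")
  v <- apply(logcpm, 2, stats::var)
  undefined <- colnames(logcpm)[v == 0]
  R <- suppressWarnings(stats::cor(logcpm))
  diag(R) <- 1
  ord <- colnames(logcpm)
  if (!length(undefined)) {
    hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
    ord <- colnames(logcpm)[hc$order]
  }
  list(cor = R, order = ord, undefined = undefined)
}

#' Principal component analysis of expression
#'
#' SVD of the per-locus-centered log2 CPM matrix with samples as
#' observations; no scaling. Variance fractions are reported per component;
#' signs are fixed so the largest-magnitude loading of each component is
#' positive.
#'
#' @param logcpm numeric matrix, loci x samples.
#' @param n_components number of components to report.
#' @return list with `scores` (samples x components), `loadings`,
#'   `variance_fraction`.
#' @export
pca_expression <- function(logcpm, n_components = 3) {
  if (ncol(logcpm) < 3) stopf("need at least three samples")
  if (n_components > ncol(logcpm))
    stopf("requested %d components from %d samples", n_components,
          ncol(logcpm))
  pr <- stats::prcomp(t(logcpm), center = TRUE, scale. = FALSE)
  k <- seq_len(min(n_components, ncol(pr$x)))
  scores <- pr$x[, k, drop = FALSE]
  load <- pr$rotation[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = load, variance_fraction = vf[k])
}

write_stage <- function(out_dir, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> pairwise DE -> RBBH co-assembly diagnostics ->
#' orthogroup paralog filter -> phenotype classification -> global
#' expression summaries (sample correlations, PCA). Deterministic for a
#' fixed seed. When `config$out_dir` is set, stage tables and a JSON run
#' manifest are written there.
#'
#' @param config an [analysis_config()].
#' @return (invisibly) a list with the stage outputs: `sim`, `de`,
#'   `diagnostics`, `og_filter`, `phenotypes`, `global`, `manifest`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- character(0)

  # --- input: simulate or read ------------------------------------------
  if (!is.null(config$counts_file)) {
    counts <- read_count_matrix(config$counts_file)
    samples <- read_sample_sheet(config$samples_file)
    check_samples(samples, counts)
    sim <- list(counts = counts, samples = samples, truth = NULL)
  } else {
    cfg <- do.call(sim_config, c(list(n_loci = config$n_loci,
                                      seed = config$seed),
                                 config$extra))
    sim <- simulate_counts(cfg)
    sim <- inject_split_orthologs(sim, config$split_fraction)
    sim <- inject_de_paralogs(sim, config$paralog_fraction)
  }
  taxa <- unique(sim$samples$taxon)
  stages <- c(stages, "input")

  # --- pairwise DE -------------------------------------------------------
  dr <- run_pairwise_de(sim$counts, sim$samples, alpha = config$alpha,
                        min_cpm = config$min_cpm)
  stages <- c(stages, "de")

  # --- RBBH co-assembly diagnostics (parental comparison) ---------------
  diagnostics <- NULL
  if (!is.null(sim$truth)) {
    hits <- emit_hit_table(sim$truth, noise_hits = config$noise_hits,
                           seed = config$seed + 307L,
                           ortholog_fraction = config$ortholog_fraction)
    parental <- paste(taxa[1], taxa[2], sep = "_")
    lin <- lineage_label(taxa[1:2])
    pairs <- if (nrow(hits))
      reciprocal_best_hits(hits, lin[1], lin[2]) else NULL
    if (!is.null(pairs) && nrow(pairs)) {
      classes <- classify_pairs_de(pairs, dr$de[[parental]])
      ct <- coassembly_chi2(classes, marginal = config$chi2_marginal)
      dir <- if (any(classes$category == "both"))
        direction_partition(classes) else NULL
      diagnostics <- list(hits = hits, pairs = pairs, classes = classes,
                          contingency = ct, direction = dir)
    }
  }
  stages <- c(stages, "diagnostics")

  # --- orthogroup paralog filter ----------------------------------------
  og_sim <- simulate_orthogroup_sequences(
    config$n_ogs, paralog_fraction = config$og_paralog_fraction,
    seed = config$seed + 401L)
  og_filter <- filter_paralogous_orthogroups(
    og_sim$ogs, og_sim$sequences, focal_genus = "Argyranthemum",
    k = config$k)
  stages <- c(stages, "og_filter")

  # --- phenotype classification -----------------------------------------
  phenotypes <- NULL
  if (length(taxa) == 4) {
    rules <- phenotype_rules(taxa[1:2], taxa[3:4])
    logcpm <- cpm_matrix(sim$counts, dr$factors, log2_transform = FALSE)
    gm <- vapply(taxa, function(tx)
      rowMeans(logcpm[, sim$samples$sample[sim$samples$taxon == tx],
                      drop = FALSE]),
      numeric(nrow(logcpm)))
    phenotypes <- classify_all(dr$de[rules$comparisons], gm, rules)
    phenotypes$bias <- lapply(taxa[3:4], function(h)
      parent_bias_summary(phenotypes$counts, h, taxa[1:2]))
    phenotypes$novel_total <- novel_total(phenotypes$counts, taxa[3:4])
  }
  stages <- c(stages, "phenotypes")

  # --- global expression summaries --------------------------------------
  logcpm2 <- cpm_matrix(sim$counts, dr$factors, log2_transform = TRUE,
                        pseudocount = config$pseudocount)
  global <- list(correlation = sample_correlation_matrix(logcpm2),
                 pca = pca_expression(logcpm2))
  stages <- c(stages, "global")

  manifest <- list(package = "orthoDE",
                   version = as.character(utils::packageVersion("orthoDE")),
                   seed = config$seed, alpha = config$alpha,
                   n_loci = config$n_loci,
                   split_fraction = config$split_fraction,
                   paralog_fraction = config$paralog_fraction,
                   stages = stages,
                   timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
    write_sample_sheet(sim$samples, file.path(out_dir, "samples.tsv"))
    if (!is.null(sim$truth)) write_stage(out_dir, "truth", sim$truth)
    for (nm in names(dr$de)) write_stage(out_dir, paste0("de_", nm), dr$de[[nm]])
    if (!is.null(diagnostics)) {
      write_hit_table(diagnostics$hits, file.path(out_dir, "hits.tsv"))
      write_stage(out_dir, "rbbh_pairs", diagnostics$classes)
    }
    write_stage(out_dir, "og_filter_calls", og_filter$calls)
    if (!is.null(phenotypes)) {
      write_stage(out_dir, "phenotype_calls", phenotypes$calls)
      write_stage(out_dir, "phenotype_counts", phenotypes$counts)
    }
    write_stage(out_dir, "pca_scores",
                data.frame(sample = rownames(global$pca$scores),
                           global$pca$scores))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(sim = sim, de = dr, diagnostics = diagnostics,
                 og_filter = og_filter, phenotypes = phenotypes,
                 global = global, manifest = manifest))
}
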