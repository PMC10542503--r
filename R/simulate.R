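#' Default expression-phenotype fractions for the simulator
#'
#' Fractions of loci assigned to each truth class, loosely mirroring the
#' relative abundances observed in four-taxon parental/hybrid leaf
#' transcriptomes: parental divergence is the most common class, parent-like
#' inheritance in the hybrids is an order of magnitude rarer per class, and
#' novel (transgressive) expression is rarer still. The remainder of loci
#' carry no true between-taxon difference.
#'
#' @param parents,hybrids taxon labels used to build class names.
#' @return named numeric vector of fractions summing to well below 1.
#' @export
default_phenotype_fractions <- function(parents = c("bro", "fru"),
                                        hybrids = c("sun", "lem")) {
  h1 <- hybrids[1]; h2 <- hybrids[2]
  p1 <- parents[1]; p2 <- parents[2]
  out <- c(0.05,
           0.01, 0.01, 0.01, 0.01, 0.01, 0.01,
           0.005, 0.005, 0.005,
           0)
  names(out) <- c("parental_de",
                  paste0(h1, "_", p1, "_like"), paste0(h1, "_", p2, "_like"),
                  paste0(h2, "_", p1, "_like"), paste0(h2, "_", p2, "_like"),
                  paste0("both_", p1, "_like"), paste0("both_", p2, "_like"),
                  paste0("novel_", h1), paste0("novel_", h2), "novel_both",
                  "hybrid_de")
  out
}

#' Simulation configuration
#'
#' Collects the parameters of the synthetic RNA-seq experiment: four taxa
#' (two parents, two hybrids), a fixed number of replicates per taxon,
#' negative-binomial counts with a common dispersion, and configurable
#' fractions of loci carrying each expression-phenotype truth class plus
#' split-ortholog / DE-paralog assembly artifacts.
#'
#' The negative binomial is parameterized by mean and dispersion with
#' variance `mu + dispersion * mu^2`; dispersion 0 degenerates to Poisson.
#' Per-locus baseline means are drawn lognormal with median `baseline_mean`
#' so that simulated depth spans roughly an order of magnitude, as in real
#' count data.
#'
#' @param n_loci number of loci to simulate.
#' @param n_reps replicates per taxon (>= 2).
#' @param taxa ordered taxon labels; the first two are the parents, any
#'   further ones the hybrids.
#' @param baseline_mean median expected count per locus (> 0).
#' @param baseline_sdlog lognormal sdlog of per-locus baselines.
#' @param dispersion NB dispersion (>= 0).
#' @param lib_sizes optional per-sample relative depth factors (> 0), length
#'   `n_reps * length(taxa)`; default all 1.
#' @param phenotype_fractions named fractions per truth class, each in
#'   \[0,1\] and summing to <= 1; the remainder are null loci.
#' @param effect_size log2 fold change applied to DE contrasts (> 0).
#' @param split_fraction,paralog_fraction fractions of eligible loci turned
#'   into split-ortholog / DE-paralog artifact pairs by the inject functions.
#' @param leak_rate fraction of a split locus's counts leaking into the
#'   partner transcript (avoids degenerate all-zero rows).
#' @param hybrid_split_lineage parent whose lineage the hybrids' reads follow
#'   at split loci (the hybrids' genomes are biased towards one parent).
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_loci,
                       n_reps = 6,
                       taxa = c("bro", "fru", "sun", "lem"),
                       baseline_mean = 100,
                       baseline_sdlog = 0.7,
                       dispersion = 0.1,
                       lib_sizes = NULL,
                       phenotype_fractions = NULL,
                       effect_size = 3,
                       split_fraction = 0,
                       paralog_fraction = 0,
                       leak_rate = 0.01,
                       hybrid_split_lineage = taxa[1],
                       seed = 1) {
  if (length(taxa) < 2) stopf("need at least two taxa")
  parents <- taxa[1:2]
  hybrids <- if (length(taxa) > 2) taxa[-(1:2)] else character(0)
  if (is.null(phenotype_fractions)) {
    phenotype_fractions <- if (length(hybrids) == 2)
      default_phenotype_fractions(parents, hybrids)
    else c(parental_de = 0.05)
  }
  if (n_loci < 1) stopf("'n_loci' must be positive")
  if (n_reps < 2) stopf("'n_reps' must be >= 2")
  if (baseline_mean <= 0) stopf("'baseline_mean' must be > 0")
  if (dispersion < 0) stopf("'dispersion' must be >= 0")
  if (effect_size <= 0) stopf("'effect_size' must be > 0")
  bad <- phenotype_fractions < 0 | phenotype_fractions > 1
  if (any(bad)) stopf("phenotype fractions must lie in [0, 1]")
  if (sum(phenotype_fractions) > 1)
    stopf("phenotype fractions sum to %.3f > 1", sum(phenotype_fractions))
  for (f in c(split_fraction, paralog_fraction, leak_rate))
    if (f < 0 || f > 1) stopf("artifact fractions must lie in [0, 1]")
  n_samples <- n_reps * length(taxa)
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples || any(lib_sizes <= 0))
    stopf("'lib_sizes' must be %d positive values", n_samples)
  structure(list(n_loci = as.integer(n_loci), n_reps = as.integer(n_reps),
                 taxa = taxa, parents = parents, hybrids = hybrids,
                 baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, lib_sizes = lib_sizes,
                 phenotype_fractions = phenotype_fractions,
                 effect_size = effect_size,
                 split_fraction = split_fraction,
                 paralog_fraction = paralog_fraction,
                 leak_rate = leak_rate,
                 hybrid_split_lineage = hybrid_split_lineage,
                 seed = as.integer(seed)),
            class = "sim_config")
}

lineage_label <- function(parent) paste0(parent, "lin")

# per-taxon true mean multipliers (log2 scale) for one locus of a given
# class; may draw from the RNG (dominance direction of parental-DE loci)
class_log2_shift <- function(label, sign, e, taxa, parents, hybrids) {
  shift <- stats::setNames(rep(0, length(taxa)), taxa)
  p1 <- parents[1]; p2 <- parents[2]
  if (label == "none") return(shift)
  if (label == "parental_de") {
    # expression inheritance with shared dominance: both hybrids track the
    # same randomly chosen parent (detectably intermediate inheritance
    # would present as shared-novel expression, which real data rarely show)
    shift[p1] <- sign * e
    if (length(hybrids) && stats::runif(1) < 0.5) shift[hybrids] <- sign * e
    return(shift)
  }
  if (label == "hybrid_de") {
    shift[hybrids[1]] <- sign * e; return(shift)
  }
  if (startsWith(label, "novel_")) {
    who <- sub("^novel_", "", label)
    tg <- if (who == "both") hybrids else who
    shift[tg] <- sign * e; return(shift)
  }
  # parent-like classes: parents differ by e; the named hybrid(s) track the
  # named parent, any unnamed hybrid inherits dominantly from a random
  # parent (a detectably intermediate hybrid would register as novel)
  shift[p1] <- sign * e
  parts <- strsplit(label, "_")[[1]]       # <hybrid|both> <parent> like
  who <- parts[1]; like <- parts[2]
  tg <- if (who == "both") hybrids else who
  other <- setdiff(hybrids, tg)
  shift[tg] <- if (like == p1) sign * e else 0
  if (length(other))
    shift[other] <- if (stats::runif(1) < 0.5) sign * e else 0
  shift
}

#' Simulate a count matrix with known expression-phenotype truth
#'
#' Draws a loci x samples negative-binomial count matrix for the configured
#' taxa. A configured fraction of loci belongs to each truth class; for those
#' loci the per-taxon means differ by `effect_size` log2 units in the pattern
#' the class implies (parent-like hybrids track one parent, novel hybrids are
#' transgressive, hybrids of purely parental-DE loci sit at the geometric
#' midpoint). Identical configurations give identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (integer matrix, transcript ids
#'   `<lineage>|<locus>` as rownames), `samples` (sample sheet), `truth`
#'   (one row per transcript: class label, lineage, artifact status, true
#'   per-taxon means) and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_loci
  taxa <- config$taxa
  loci <- sprintf("LOC%06d", seq_len(n))
  base <- stats::rlnorm(n, log(config$baseline_mean), config$baseline_sdlog)
  fr <- config$phenotype_fractions
  labels <- sample(c(names(fr), "none"), n, replace = TRUE,
                   prob = c(fr, 1 - sum(fr)))
  signs <- sample(c(-1L, 1L), n, replace = TRUE)
  lineage <- sample(lineage_label(config$parents), n, replace = TRUE)

  shift <- t(vapply(seq_len(n), function(i)
    class_log2_shift(labels[i], signs[i], config$effect_size,
                     taxa, config$parents, config$hybrids),
    numeric(length(taxa))))
  colnames(shift) <- taxa
  means <- base * 2^shift                   # loci x taxa true means

  samples <- data.frame(
    sample = paste0(rep(taxa, each = config$n_reps), "_",
                    rep(seq_len(config$n_reps), length(taxa))),
    taxon = rep(taxa, each = config$n_reps),
    replicate = rep(seq_len(config$n_reps), length(taxa)),
    stringsAsFactors = FALSE)
  libfac <- config$lib_sizes

  counts <- matrix(0L, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mu <- means[, samples$taxon[j]] * libfac[j]
    counts[, j] <- if (config$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(n, mu)
  }
  tid <- paste0(lineage, "|", loci)
  dimnames(counts) <- list(tid, samples$sample)

  truth <- data.frame(transcript_id = tid, locus_id = loci,
                      lineage = lineage, label = labels, sign = signs,
                      artifact = "none", partner_id = NA_character_,
                      stringsAsFactors = FALSE)
  mcols <- as.data.frame(means)
  names(mcols) <- paste0("mean_", taxa)
  truth <- cbind(truth, mcols)
  rownames(truth) <- NULL
  list(counts = counts, samples = samples, truth = truth, config = config)
}

split_sample_groups <- function(sim, hybrid_lineage) {
  cfg <- sim$config
  p1 <- cfg$parents[1]; p2 <- cfg$parents[2]
  hy <- cfg$hybrids
  g1 <- c(p1, if (identical(hybrid_lineage, p1)) hy)
  g2 <- c(p2, if (identical(hybrid_lineage, p2)) hy)
  # hybrids not assigned to either parent default to the first parent's side
  if (length(hy) && !hybrid_lineage %in% c(p1, p2)) g1 <- c(g1, hy)
  list(g1 = sim$samples$sample[sim$samples$taxon %in% g1],
       g2 = sim$samples$sample[sim$samples$taxon %in% g2],
       taxa1 = g1, taxa2 = g2)
}

select_eligible <- function(truth, fraction) {
  eligible <- which(truth$label == "none" & truth$artifact == "none")
  eligible[stats::runif(length(eligible)) < fraction]
}

#' Inject split-ortholog artifacts
#'
#' Replaces a fraction of null loci by two transcripts that mimic a failed
#' co-assembly: one transcript carries the counts of the first parent's
#' lineage (plus the hybrids, by default), the other the second parent's,
#' with a small leak of reads to the opposite transcript. Count mass per
#' sample is conserved exactly. Each eligible locus is selected
#' independently with probability `fraction`.
#'
#' @param sim output of [simulate_counts()] (possibly already injected).
#' @param fraction selection probability per eligible locus, in \[0,1\].
#' @param seed RNG seed (default derived from the simulation seed).
#' @param leak_rate per-read probability of leaking to the partner.
#' @param hybrid_lineage parent lineage the hybrids' reads follow.
#' @return the modified simulation list.
#' @export
inject_split_orthologs <- function(sim, fraction,
                                   seed = sim$config$seed + 101L,
                                   leak_rate = sim$config$leak_rate,
                                   hybrid_lineage = sim$config$hybrid_split_lineage) {
  if (fraction < 0 || fraction > 1) stopf("'fraction' must lie in [0, 1]")
  if (fraction == 0) return(sim)
  set.seed(seed)
  cfg <- sim$config
  gr <- split_sample_groups(sim, hybrid_lineage)
  idx <- select_eligible(sim$truth, fraction)
  if (!length(idx)) return(sim)

  l1 <- lineage_label(cfg$parents[1]); l2 <- lineage_label(cfg$parents[2])
  counts <- sim$counts
  truth <- sim$truth
  new_rows <- list(); new_truth <- list()
  for (i in idx) {
    y <- counts[i, ]
    locus <- truth$locus_id[i]
    id1 <- paste0(l1, "|", locus); id2 <- paste0(l2, "|", locus)
    leak_from_1 <- stats::rbinom(length(gr$g1), y[gr$g1], leak_rate)
    leak_from_2 <- stats::rbinom(length(gr$g2), y[gr$g2], leak_rate)
    t1 <- y; t2 <- y
    t1[gr$g1] <- y[gr$g1] - leak_from_1; t2[gr$g1] <- leak_from_1
    t2[gr$g2] <- y[gr$g2] - leak_from_2; t1[gr$g2] <- leak_from_2
    counts[i, ] <- t1
    rownames(counts)[i] <- id1
    new_rows[[length(new_rows) + 1L]] <- t2

    m <- as.numeric(truth[i, paste0("mean_", cfg$taxa)])
    m1 <- ifelse(cfg$taxa %in% gr$taxa1, m * (1 - leak_rate), m * leak_rate)
    m2 <- ifelse(cfg$taxa %in% gr$taxa2, m * (1 - leak_rate), m * leak_rate)
    truth$transcript_id[i] <- id1
    truth$lineage[i] <- l1
    truth$artifact[i] <- "split_ortholog"
    truth$partner_id[i] <- id2
    truth[i, paste0("mean_", cfg$taxa)] <- as.list(m1)
    tr <- truth[i, ]
    tr$transcript_id <- id2; tr$lineage <- l2; tr$partner_id <- id1
    tr[paste0("mean_", cfg$taxa)] <- as.list(m2)
    new_truth[[length(new_truth) + 1L]] <- tr
  }
  extra <- do.call(rbind, new_rows)
  rownames(extra) <- vapply(new_truth, function(x) x$transcript_id, "")
  sim$counts <- rbind(counts, extra)
  sim$truth <- rbind(truth, do.call(rbind, new_truth))
  rownames(sim$truth) <- NULL
  sim
}

#' Inject DE-paralog artifacts
#'
#' Replaces a fraction of null loci by two transcripts representing
#' non-co-assembling paralogs that are both genuinely DE between the parents
#' in the same direction. Counts for both paralogs are drawn fresh from the
#' configured NB model.
#'
#' @inheritParams inject_split_orthologs
#' @export
inject_de_paralogs <- function(sim, fraction,
                               seed = sim$config$seed + 211L) {
  if (fraction < 0 || fraction > 1) stopf("'fraction' must lie in [0, 1]")
  if (fraction == 0) return(sim)
  set.seed(seed)
  cfg <- sim$config
  idx <- select_eligible(sim$truth, fraction)
  if (!length(idx)) return(sim)

  l1 <- lineage_label(cfg$parents[1]); l2 <- lineage_label(cfg$parents[2])
  counts <- sim$counts
  truth <- sim$truth
  new_rows <- list(); new_truth <- list()
  draw <- function(mu_taxa) {
    mu <- mu_taxa[sim$samples$taxon] * cfg$lib_sizes
    if (cfg$dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    else stats::rpois(length(mu), mu)
  }
  for (i in idx) {
    locus <- truth$locus_id[i]
    id1 <- paste0(l1, "|", locus); id2 <- paste0(l2, "|", locus)
    s <- sample(c(-1L, 1L), 1L)
    mk_means <- function(b) {
      sh <- class_log2_shift("parental_de", s, cfg$effect_size,
                             cfg$taxa, cfg$parents, cfg$hybrids)
      stats::setNames(b * 2^sh, cfg$taxa)
    }
    b1 <- stats::rlnorm(1, log(cfg$baseline_mean), cfg$baseline_sdlog)
    b2 <- stats::rlnorm(1, log(cfg$baseline_mean), cfg$baseline_sdlog)
    m1 <- mk_means(b1); m2 <- mk_means(b2)
    counts[i, ] <- draw(m1)
    rownames(counts)[i] <- id1
    new_rows[[length(new_rows) + 1L]] <- draw(m2)

    truth$transcript_id[i] <- id1
    truth$lineage[i] <- l1
    truth$artifact[i] <- "de_paralog"
    truth$partner_id[i] <- id2
    truth$sign[i] <- s
    truth[i, paste0("mean_", cfg$taxa)] <- as.list(m1)
    tr <- truth[i, ]
    tr$transcript_id <- id2; tr$lineage <- l2; tr$partner_id <- id1
    tr[paste0("mean_", cfg$taxa)] <- as.list(m2)
    new_truth[[length(new_truth) + 1L]] <- tr
  }
  extra <- do.call(rbind, new_rows)
  rownames(extra) <- vapply(new_truth, function(x) x$transcript_id, "")
  sim$counts <- rbind(counts, extra)
  sim$truth <- rbind(truth, do.call(rbind, new_truth))
  rownames(sim$truth) <- NULL
  sim
}

#' Emit a BLAST-style hit table for a synthetic truth set
#'
#' Every split-ortholog / DE-paralog partner pair appears as a mutual best
#' hit (high, tie-free bitscores). Optionally, a fraction of the ordinary
#' (artifact-free) transcripts is paired across lineages as additional
#' mutual best hits, emulating the gene-family counterparts that dominate a
#' real self-BLAST's reciprocal-best set; their DE status is whatever their
#' loci happen to have. Finally, `noise_hits` random one-directional
#' background hits with strictly lower bitscores are appended; because a
#' reciprocal pair needs hits in both directions, noise can never form one.
#'
#' @param truth truth data.frame from the simulation.
#' @param noise_hits number of random background hits.
#' @param seed RNG seed.
#' @param ortholog_fraction fraction of ordinary transcripts (per lineage)
#'   emitted as cross-lineage mutual best pairs.
#' @return a 12-column hit table in BLAST tabular (outfmt 6) layout.
#' @export
emit_hit_table <- function(truth, noise_hits = 0, seed = 1,
                           ortholog_fraction = 0) {
  if (ortholog_fraction < 0 || ortholog_fraction > 1)
    stopf("'ortholog_fraction' must lie in [0, 1]")
  set.seed(seed)
  prt <- truth[truth$artifact != "none" & !is.na(truth$partner_id), ,
               drop = FALSE]
  keep <- prt$transcript_id < prt$partner_id
  pairs <- prt[keep, c("transcript_id", "partner_id"), drop = FALSE]
  if (ortholog_fraction > 0) {
    ord <- truth[truth$artifact == "none", , drop = FALSE]
    sets <- split(ord$transcript_id, ord$lineage)
    if (length(sets) >= 2) {
      m <- round(ortholog_fraction * min(lengths(sets)))
      if (m > 0) {
        a <- sample(sets[[1]], m)
        b <- sample(sets[[2]], m)
        pairs <- rbind(pairs, data.frame(transcript_id = a, partner_id = b,
                                         stringsAsFactors = FALSE))
      }
    }
  }

  mk_row <- function(q, s, bit, pid, ev) {
    len <- round(stats::runif(length(q), 200, 500))
    data.frame(qseqid = q, sseqid = s, pident = round(pid, 2),
               length = len, mismatch = round(len * (100 - pid) / 100),
               gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = len,
               evalue = signif(ev, 3), bitscore = round(bit, 1),
               stringsAsFactors = FALSE)
  }
  out <- list()
  np <- nrow(pairs)
  if (np) {
    bit_f <- stats::runif(np, 450, 900)
    bit_r <- stats::runif(np, 450, 900)
    pid <- stats::runif(np, 97, 99.9)
    out$fwd <- mk_row(pairs$transcript_id, pairs$partner_id, bit_f, pid, 1e-50)
    out$rev <- mk_row(pairs$partner_id, pairs$transcript_id, bit_r, pid, 1e-50)
  }
  if (noise_hits > 0) {
    lin <- sub("\\|.*", "", truth$transcript_id)
    sets <- split(truth$transcript_id, lin)
    if (length(sets) >= 2) {
      q <- sample(sets[[1]], noise_hits, replace = TRUE)
      s <- sample(sets[[2]], noise_hits, replace = TRUE)
      flip <- stats::runif(noise_hits) < 0.5
      tmp <- q[flip]; q[flip] <- s[flip]; s[flip] <- tmp
      bit <- stats::runif(noise_hits, 50, 400)
      pid <- stats::runif(noise_hits, 80, 96)
      ev <- 10^-stats::runif(noise_hits, 5, 20)
      ns <- mk_row(q, s, bit, pid, ev)
      key <- paste(ns$qseqid, ns$sseqid)
      # background hits stay one-directional and never overwrite a pair
      drop <- duplicated(key) | key %in% paste(ns$sseqid, ns$qseqid) |
        ns$qseqid == ns$sseqid
      if (nrow(pairs)) {
        pkey <- c(paste(pairs$transcript_id, pairs$partner_id),
                  paste(pairs$partner_id, pairs$transcript_id))
        drop <- drop | key %in% pkey
      }
      out$noise <- ns[!drop, , drop = FALSE]
    }
  }
  if (!length(out)) return(empty_hit_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hit_table", "data.frame")
  res
}

jc_mutate <- function(seq, p) {
  # Jukes-Cantor-style uniform substitution: each site replaced with
  # probability p by one of the three other bases
  hit <- which(stats::runif(length(seq)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) seq[i] <- sample(setdiff(bases, seq[i]), 1L)
  }
  seq
}

#' Simulate orthogroup sequence sets with known monophyly status
#'
#' Each orthogroup contains one sequence per focal-genus taxon plus one per
#' outgroup genus, evolved down a fixed species tree by uniform (Jukes-Cantor
#' style) substitutions. A configurable fraction of orthogroups is
#' contaminated with a paralog: an extra focal-genus-labelled sequence that
#' descends from the outgroup side of the tree, making the focal genus
#' non-monophyletic in the gene tree.
#'
#' @param n_ogs number of orthogroups.
#' @param paralog_fraction fraction of orthogroups contaminated.
#' @param divergence per-site substitution probability per tree unit,
#'   in (0, 0.5).
#' @param seed RNG seed.
#' @param seq_length sequence length in bp.
#' @param focal_taxa taxa of the focal genus.
#' @param focal_genus genus label for the focal taxa.
#' @param outgroups named character vector genus -> taxon label.
#' @return list with `sequences` (named character vector of DNA strings),
#'   `ogs` (an orthogroup set, see [parse_orthogroups()]) and `truth`
#'   (data.frame og / contaminated).
#' @export
simulate_orthogroup_sequences <- function(n_ogs, paralog_fraction = 0,
                                          divergence = 0.05, seed = 1,
                                          seq_length = 500,
                                          focal_taxa = c("bro", "fru", "sun", "lem"),
                                          focal_genus = "Argyranthemum",
                                          outgroups = c(Helianthus = "hel",
                                                        Lactuca = "lac")) {
  if (divergence <= 0 || divergence >= 0.5)
    stopf("'divergence' must lie in (0, 0.5)")
  if (paralog_fraction < 0 || paralog_fraction > 1)
    stopf("'paralog_fraction' must lie in [0, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  contaminated <- stats::runif(n_ogs) < paralog_fraction
  seqs <- character(0)
  members <- list()
  for (g in seq_len(n_ogs)) {
    og <- sprintf("OG%04d", g)
    root <- sample(bases, seq_length, replace = TRUE)
    anc_foc <- jc_mutate(root, divergence)
    anc_out <- jc_mutate(root, divergence)
    anc12 <- jc_mutate(anc_foc, divergence)
    anc34 <- jc_mutate(anc_foc, divergence)
    tips <- list()
    tips[[focal_taxa[1]]] <- jc_mutate(anc12, divergence)
    tips[[focal_taxa[2]]] <- jc_mutate(anc12, divergence)
    tips[[focal_taxa[3]]] <- jc_mutate(anc34, divergence)
    tips[[focal_taxa[4]]] <- jc_mutate(anc34, divergence)
    # first outgroup genus gets its own short stem so a paralog can be
    # grafted strictly inside its clade
    stem1 <- jc_mutate(anc_out, divergence)
    tips[[outgroups[[1]]]] <- jc_mutate(stem1, divergence)
    for (og_genus in names(outgroups)[-1])
      tips[[outgroups[[og_genus]]]] <- jc_mutate(anc_out, 2 * divergence)
    taxon <- names(tips)
    tid <- paste0(og, "_", taxon)
    if (contaminated[g]) {
      # paralog: sister to the first outgroup tip but labelled focal
      tips[[length(tips) + 1L]] <- jc_mutate(stem1, divergence)
      taxon <- c(taxon, focal_taxa[1])
      tid <- c(tid, paste0(og, "_paralog"))
    }
    genus <- ifelse(taxon %in% focal_taxa, focal_genus,
                    names(outgroups)[match(taxon, outgroups)])
    sq <- vapply(tips, paste0, "", collapse = "")
    names(sq) <- tid
    seqs <- c(seqs, sq)
    members[[g]] <- data.frame(og = og, transcript = tid, taxon = taxon,
                               genus = genus, stringsAsFactors = FALSE)
  }
  mem <- do.call(rbind, members)
  rownames(mem) <- NULL
  ogs <- new_orthogroup_set(sprintf("OG%04d", seq_len(n_ogs)), mem)
  truth <- data.frame(og = sprintf("OG%04d", seq_len(n_ogs)),
                      contaminated = contaminated, stringsAsFactors = FALSE)
  list(sequences = seqs, ogs = ogs, truth = truth)
}
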