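# Two-sided conditional exact p-values for group-A locus sums.
#
# Under a common-dispersion NB model with equal per-sample means and
# equalized library sizes, the sum of the nA group-A counts is NB with size
# nA/phi, and conditional on the overall locus total s the group-A sum has a
# (negative-hypergeometric) distribution obtained by normalizing the product
# of the two group-sum NB densities over x = 0..s. The p-value is twice the
# smaller tail (both tails include the observed outcome), capped at 1.
# phi = 0 degenerates to the conditional binomial.
cond_exact_pvals <- function(sA, s, nA, nB, phi) {
  p <- rep(1, length(s))
  pos <- s > 0
  if (!any(pos)) return(p)
  if (phi <= 0) {
    pr <- nA / (nA + nB)
    lower <- stats::pbinom(sA[pos], s[pos], pr)
    upper <- stats::pbinom(sA[pos] - 1, s[pos], pr, lower.tail = FALSE)
    p[pos] <- pmin(1, 2 * pmin(lower, upper))
    return(p)
  }
  ord <- order(s)
  ord <- ord[s[ord] > 0]
  sizeA <- nA / phi; sizeB <- nB / phi
  # chunk loci of similar total so the enumeration matrix stays small
  budget <- 2e6
  k <- 1L
  n_ord <- length(ord)
  while (k <= n_ord) {
    len <- 1L
    while (k + len <= n_ord &&
           (s[ord[k + len]] + 1) * (len + 1) <= budget) len <- len + 1L
    idx <- ord[k:(k + len - 1L)]
    k <- k + len
    smax <- max(s[idx])
    x <- 0:smax
    m <- s[idx] / (nA + nB)
    Xm <- matrix(x, smax + 1L, length(idx))
    MUA <- matrix(nA * m, smax + 1L, length(idx), byrow = TRUE)
    MUB <- matrix(nB * m, smax + 1L, length(idx), byrow = TRUE)
    Sm <- matrix(s[idx], smax + 1L, length(idx), byrow = TRUE)
    Xb <- Sm - Xm
    valid <- Xb >= 0
    Xb[!valid] <- 0L
    LL <- stats::dnbinom(Xm, size = sizeA, mu = MUA, log = TRUE) +
      stats::dnbinom(Xb, size = sizeB, mu = MUB, log = TRUE)
    LL[!valid] <- -Inf
    cmax <- apply(LL, 2, max)
    P <- exp(sweep(LL, 2, cmax, "-"))
    tot <- colSums(P)
    cum <- apply(P, 2, cumsum)
    iobs <- sA[idx] + 1L
    lower <- cum[cbind(iobs, seq_along(idx))] / tot
    lower_excl <- ifelse(sA[idx] == 0, 0,
                         cum[cbind(pmax(iobs - 1L, 1L), seq_along(idx))] / tot)
    upper <- 1 - lower_excl
    p[idx] <- pmin(1, 2 * pmin(lower, upper))
  }
  p
}

#' Pairwise NB exact test between two taxa
#'
#' Library sizes are first equalized (using the effective, TMM-scaled sizes
#' when `factors` is supplied) and rounded. For each locus the two-sided
#' p-value is the doubled smaller tail probability of the observed group-A
#' sum conditional on the locus total, under a negative binomial with the
#' given common dispersion; dispersion 0 reduces to a conditional binomial
#' test. The log2 fold change (second taxon vs first) is computed from the
#' equalized group means after adding a small shrinkage pseudo-count to each
#' group mean, so it is finite at zero counts.
#'
#' @param counts count matrix.
#' @param samples sample sheet (columns sample, taxon, replicate).
#' @param taxon_a,taxon_b the ordered taxon pair; the reported fold change
#'   is `taxon_b` relative to `taxon_a`.
#' @param dispersion a scalar dispersion or an
#'   [estimate_common_dispersion()] result.
#' @param factors optional TMM factors (for the full matrix).
#' @param prior_count shrinkage pseudo-count added to each group mean.
#' @return data.frame with columns locus, logFC, pvalue.
#' @export
nb_exact_test <- function(counts, samples, taxon_a, taxon_b, dispersion,
                          factors = NULL, prior_count = 0.125) {
  check_count_matrix(counts)
  check_samples(samples, counts)
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% samples$taxon) stopf("unknown taxon label '%s'", tx)
  phi <- if (inherits(dispersion, "dispersion_estimate")) dispersion$phi
         else as.numeric(dispersion)
  if (phi < 0) stopf("dispersion must be >= 0")
  sa <- samples$sample[samples$taxon == taxon_a]
  sb <- samples$sample[samples$taxon == taxon_b]
  if (length(sa) < 2 || length(sb) < 2)
    stopf("both taxa need >= 2 replicates")
  sub <- counts[, c(sa, sb), drop = FALSE]
  fsub <- if (!is.null(factors)) factors[c(sa, sb)] else NULL
  eq <- equalize_libraries(sub, fsub)
  nA <- length(sa); nB <- length(sb)
  SA <- rowSums(eq[, sa, drop = FALSE])
  SB <- rowSums(eq[, sb, drop = FALSE])
  pv <- cond_exact_pvals(SA, SA + SB, nA, nB, phi)
  mA <- SA / nA + prior_count
  mB <- SB / nB + prior_count
  data.frame(locus = rownames(counts), logFC = log2(mB / mA), pvalue = pv,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, preserving input order.
#' A validating wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0,1\].
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential expression at an FDR threshold
#'
#' Flags loci with `qvalue < alpha` (strict inequality) as DE and assigns a
#' direction from the sign of the fold change. No fold-change cutoff is
#' applied: significance alone decides.
#'
#' @param results data.frame with columns locus, logFC, pvalue and
#'   optionally qvalue (computed by [bh_adjust()] if absent).
#' @param alpha FDR threshold in (0, 1).
#' @return the input with columns qvalue, de_flag and direction
#'   (`up_in_first` / `up_in_second` / `none`; logFC is second vs first).
#' @export
call_de <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must lie in (0, 1)")
  if (!all(c("locus", "logFC", "pvalue") %in% names(results)))
    stopf("'results' must have columns locus, logFC, pvalue")
  if (is.null(results$qvalue)) results$qvalue <- bh_adjust(results$pvalue)
  stopifnot(all(results$qvalue >= results$pvalue - 1e-12))
  results$de_flag <- results$qvalue < alpha
  results$direction <- ifelse(!results$de_flag, "none",
                              ifelse(results$logFC < 0, "up_in_first",
                                     "up_in_second"))
  results
}

#' All ordered pairwise comparisons among taxa
#'
#' @param taxa ordered taxon labels.
#' @return data.frame with columns first, second, name (`first_second`).
#' @export
taxa_pairs <- function(taxa) {
  idx <- utils::combn(seq_along(taxa), 2)
  data.frame(first = taxa[idx[1, ]], second = taxa[idx[2, ]],
             name = paste(taxa[idx[1, ]], taxa[idx[2, ]], sep = "_"),
             stringsAsFactors = FALSE)
}

#' Run pairwise DE across taxa
#'
#' Computes TMM factors once, estimates a common dispersion across all
#' groups, runs the NB exact test for every requested taxon pair and applies
#' BH within each comparison. Optionally drops loci below a CPM floor in
#' every sample before testing.
#'
#' @param counts count matrix.
#' @param samples sample sheet.
#' @param pairs data.frame as from [taxa_pairs()]; default all pairs of the
#'   taxa in sample-sheet order.
#' @param alpha FDR threshold.
#' @param min_cpm optional CPM floor: keep loci with CPM >= `min_cpm` in at
#'   least one sample (off by default; the main analysis keeps all loci).
#' @param prior_count fold-change shrinkage pseudo-count.
#' @return list with `de` (named list of per-comparison DE tables),
#'   `factors`, `dispersion`, `pairs`.
#' @export
run_pairwise_de <- function(counts, samples, pairs = NULL, alpha = 0.05,
                            min_cpm = NULL, prior_count = 0.125) {
  check_count_matrix(counts)
  check_samples(samples, counts)
  counts <- counts[, samples$sample, drop = FALSE]
  if (is.null(pairs)) pairs <- taxa_pairs(unique(samples$taxon))
  factors <- compute_tmm_factors(counts)
  if (!is.null(min_cpm)) {
    keep <- rowSums(cpm_matrix(counts, factors) >= min_cpm) >= 1
    counts <- counts[keep, , drop = FALSE]
  }
  disp <- estimate_common_dispersion(counts, samples$taxon, factors)
  de <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- nb_exact_test(counts, samples, pairs$first[i], pairs$second[i],
                         disp, factors, prior_count)
    res$qvalue <- bh_adjust(res$pvalue)
    call_de(res, alpha)
  })
  names(de) <- pairs$name
  list(de = de, factors = factors, dispersion = disp, pairs = pairs)
}
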