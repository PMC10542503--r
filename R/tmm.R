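#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM method: for each sample
#' against a reference sample, per-locus log2 expression ratios (M-values)
#' are trimmed on both M (log ratio) and A (mean log abundance), weighted by
#' the inverse of their asymptotic binomial variance, and averaged; the
#' factor is 2 to that weighted mean. Loci with a zero count in either
#' sample of a comparison are excluded. Factors are renormalized so their
#' geometric mean is exactly 1.
#'
#' The reference sample is the one whose 75th count-fraction percentile is
#' closest to the across-sample mean, unless given explicitly.
#'
#' @param counts integer count matrix (loci x samples).
#' @param trim_m two-sided trim fraction on M-values (each tail).
#' @param trim_a two-sided trim fraction on A-values (each tail).
#' @param ref optional reference sample id.
#' @return named numeric vector of factors with attributes `ref_sample`,
#'   `trim_m`, `trim_a`; class `tmm_factors`.
#' @export
compute_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                                ref = NULL) {
  check_count_matrix(counts)
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  lib <- colSums(counts)
  if (any(lib == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref)) {
    f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref %in% colnames(counts)) stopf("unknown reference sample '%s'", ref)
  refc <- counts[, ref]
  nR <- lib[[ref]]
  f <- vapply(colnames(counts), function(k) {
    if (k == ref) return(1)
    obs <- counts[, k]
    nO <- lib[[k]]
    pos <- obs > 0 & refc > 0
    if (!any(pos)) return(1)
    o <- obs[pos]; r <- refc[pos]
    M <- log2((o / nO) / (r / nR))
    A <- 0.5 * log2((o / nO) * (r / nR))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    w <- 1 / ((nO - o) / (nO * o) + (nR - r) / (nR * r))
    fk <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    if (!is.finite(fk) || fk <= 0) 1 else fk
  }, numeric(1))
  f <- f / geomean(f)
  structure(f, ref_sample = ref, trim_m = trim_m, trim_a = trim_a,
            class = "tmm_factors")
}

#' Counts per million, optionally log2-transformed
#'
#' CPM uses the effective library size (raw library size times the TMM
#' factor). With `log2_transform = TRUE`, returns `log2(CPM + pseudocount)`.
#'
#' @param counts count matrix (loci x samples).
#' @param factors optional [compute_tmm_factors()] output for the same
#'   samples; default all 1 (raw library-size CPM).
#' @param log2_transform logical.
#' @param pseudocount added before the log transform.
#' @return numeric matrix of the same dimensions as `counts`.
#' @export
cpm_matrix <- function(counts, factors = NULL, log2_transform = FALSE,
                       pseudocount = 1) {
  check_count_matrix(counts)
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  if (!setequal(names(factors), colnames(counts)))
    stopf("normalization factors do not match the samples of 'counts'")
  eff <- colSums(counts) * factors[colnames(counts)]
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  if (log2_transform) cpm <- log2(cpm + pseudocount)
  cpm
}
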