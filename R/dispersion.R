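#' Scale samples to a common (geometric-mean) library size
#'
#' Multiplies each sample's counts by the ratio of the geometric mean of the
#' effective library sizes to its own effective library size, then rounds to
#' integers. Conditional NB inference downstream assumes equal library sizes;
#' this is the supporting adjustment.
#'
#' @param counts count matrix.
#' @param factors optional TMM factors; effective library size is
#'   `colSums(counts) * factors`.
#' @return integer matrix of equalized counts.
#' @export
equalize_libraries <- function(counts, factors = NULL) {
  check_count_matrix(counts)
  eff <- colSums(counts)
  if (!is.null(factors)) {
    if (!setequal(names(factors), colnames(counts)))
      stopf("normalization factors do not match the samples of 'counts'")
    eff <- eff * factors[colnames(counts)]
  }
  if (any(eff == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[eff == 0], collapse = ", "))
  target <- geomean(eff)
  out <- round(sweep(counts, 2, target / eff, "*"))
  storage.mode(out) <- "integer"
  out
}

# conditional (on per-group locus totals) NB log-likelihood of a common
# dispersion phi on library-size-equalized counts; groups with one
# replicate contribute zero information and cancel exactly
cond_loglik_phi <- function(phi, eq, group) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(group)) {
    Y <- eq[, group == g, drop = FALSE]
    ng <- ncol(Y)
    if (ng < 2) next
    z <- rowSums(Y)
    ll <- ll + sum(lgamma(Y + r)) - length(z) * ng * lgamma(r) -
      sum(lgamma(z + ng * r)) + length(z) * lgamma(ng * r)
  }
  ll
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the log-likelihood of the counts conditional on each locus's
#' per-group total, on library-size-equalized counts, over a single common
#' dispersion shared by all loci. The search is a coarse log-scale grid
#' followed by golden-section refinement; the estimate is clamped to be
#' non-negative (a boundary estimate near zero indicates Poisson-like data).
#'
#' @param counts count matrix.
#' @param groups factor or character vector of group (taxon) labels, one per
#'   sample, in column order.
#' @param factors optional TMM factors used for library equalization.
#' @param phi_min,phi_max search bounds for the dispersion.
#' @return list with `phi` and `method`; class `dispersion_estimate`.
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL,
                                       phi_min = 1e-4, phi_max = 4) {
  check_count_matrix(counts)
  if (all(counts == 0)) stopf("count matrix is all zero")
  group <- factor(groups)
  if (length(group) != ncol(counts))
    stopf("'groups' must have one label per sample")
  if (!any(table(group) >= 2))
    stopf("need at least one group with >= 2 replicates")
  eq <- equalize_libraries(counts, factors)
  grid <- exp(seq(log(phi_min), log(phi_max), length.out = 25))
  ll <- vapply(grid, cond_loglik_phi, numeric(1), eq = eq, group = group)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(lp) cond_loglik_phi(exp(lp), eq, group),
                         interval = log(c(lo, hi)), maximum = TRUE)
  phi <- exp(opt$maximum)
  if (cond_loglik_phi(phi, eq, group) < ll[i]) phi <- grid[i]
  structure(list(phi = max(phi, 0), method = "conditional_ml"),
            class = "dispersion_estimate")
}
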