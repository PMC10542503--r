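make_matrix <- function(v, samples = paste0("s", seq_len(ncol(v)))) {
  dimnames(v) <- list(paste0("L", seq_len(nrow(v))), samples)
  storage.mode(v) <- "integer"
  v
}

test_that("TMM factors are 1 for identical or depth-scaled samples", {
  y <- make_matrix(cbind(c(10L, 20L, 30L, 5L), c(10L, 20L, 30L, 5L)))
  f <- compute_tmm_factors(y)
  expect_equal(unname(f[1:2]), c(1, 1))

  y2 <- make_matrix(cbind(c(10L, 20L, 30L, 5L), 10L * c(10L, 20L, 30L, 5L)))
  f2 <- compute_tmm_factors(y2)
  expect_equal(unname(f2[1:2]), c(1, 1))
})

test_that("TMM matches the direct formula on an 8-locus toy", {
  set.seed(1)
  a <- c(100L, 220L, 40L, 75L, 310L, 50L, 120L, 90L)
  b <- c(95L, 230L, 38L, 8000L, 290L, 55L, 130L, 85L)   # one inflated locus
  y <- make_matrix(cbind(a, b))
  f <- compute_tmm_factors(y, ref = "s1")
  oracle <- oracle_tmm_one(b, a)
  expected <- c(1, oracle) / exp(mean(log(c(1, oracle))))
  expect_equal(unname(f[c("s1", "s2")]), expected, tolerance = 1e-12)
})

test_that("TMM factors have unit geometric mean and depth invariance", {
  set.seed(7)
  for (i in 1:5) {
    y <- make_matrix(matrix(rnbinom(200 * 4, mu = 80, size = 5), 200, 4))
    f <- compute_tmm_factors(y)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    # M- and A-values are exactly depth-invariant; the binomial precision
    # weights shift slightly with depth, so the factors match closely but
    # not bitwise
    y2 <- y
    y2[, 2] <- y2[, 2] * 7L
    expect_equal(as.numeric(compute_tmm_factors(y2, ref = "s1")),
                 as.numeric(compute_tmm_factors(y, ref = "s1")),
                 tolerance = 0.02)
  }
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  y <- make_matrix(matrix(rnbinom(500 * 6, mu = 100, size = 8), 500, 6))
  f_ref <- edgeR::calcNormFactors(y)
  f <- compute_tmm_factors(y)
  expect_equal(unname(f[colnames(y)]), unname(f_ref), tolerance = 1e-6)
})

test_that("all-zero samples are rejected by name", {
  y <- make_matrix(cbind(c(5L, 5L), c(0L, 0L)), c("good", "dead"))
  expect_error(compute_tmm_factors(y), "dead")
})

test_that("CPM is uniform for uniform counts and depth-invariant", {
  y <- make_matrix(matrix(50L, 8, 3))
  cpm <- cpm_matrix(y)
  expect_true(all(abs(cpm - 1e6 / 8) < 1e-9))
  y2 <- y
  y2[, 2] <- y2[, 2] * 2L
  expect_equal(cpm_matrix(y2)[, 2], cpm_matrix(y)[, 2])
})

test_that("CPM matches hand arithmetic on a 4x3 matrix", {
  y <- make_matrix(cbind(c(10L, 20L, 30L, 40L),
                         c(1L, 2L, 3L, 4L),
                         c(0L, 50L, 25L, 25L)))
  cpm <- cpm_matrix(y)
  expect_equal(cpm[, 1], c(L1 = 0.1, L2 = 0.2, L3 = 0.3, L4 = 0.4) * 1e6)
  expect_equal(unname(cpm[3, 2]), 3 / 10 * 1e6)
  log2cpm <- cpm_matrix(y, log2_transform = TRUE, pseudocount = 1)
  expect_equal(unname(log2cpm[1, 3]), 0)
  expect_error(cpm_matrix(y, factors = c(x = 1)), "factors")
})

test_that("common dispersion is recovered from NB and Poisson data", {
  set.seed(31)
  groups <- rep(c("a", "b"), each = 6)
  y_pois <- make_matrix(matrix(rpois(1000 * 12, 100), 1000, 12))
  est0 <- estimate_common_dispersion(y_pois, groups)
  expect_lte(est0$phi, 0.01)

  y_nb <- make_matrix(matrix(rnbinom(1000 * 12, mu = 100, size = 10),
                             1000, 12))
  est <- estimate_common_dispersion(y_nb, groups)
  expect_gte(est$phi, 0.07)
  expect_lte(est$phi, 0.13)

  zero <- make_matrix(matrix(0L, 4, 4))
  expect_error(estimate_common_dispersion(zero, rep("a", 4)), "zero")
  expect_error(estimate_common_dispersion(y_nb, 1:12), "replicates")
})

exact_toy <- function(counts_a, counts_b, phi, total = NULL) {
  # embeds the toy locus in a matrix with equal column sums so library
  # equalization is the identity
  if (is.null(total)) total <- max(counts_a, counts_b) * 3
  y <- rbind(c(counts_a, counts_b), total - c(counts_a, counts_b))
  samples <- data.frame(
    sample = paste0("s", seq_len(ncol(y))),
    taxon = rep(c("A", "B"), c(length(counts_a), length(counts_b))),
    replicate = c(seq_along(counts_a), seq_along(counts_b)))
  y <- make_matrix(y, samples$sample)
  nb_exact_test(y, samples, "A", "B", phi)[1, ]
}

test_that("exact test is symmetric at equal counts", {
  res <- exact_toy(c(20L, 20L), c(20L, 20L), phi = 0.1)
  expect_equal(res$pvalue, 1)
  expect_equal(res$logFC, 0)
})

test_that("zero dispersion reduces to the conditional binomial", {
  res <- exact_toy(c(5L, 7L), c(6L, 4L), phi = 0)
  expect_equal(res$pvalue, oracle_cond_exact_p(c(5, 7), c(6, 4), 0),
               tolerance = 1e-12)
})

test_that("exact test equals the convolution-enumeration oracle", {
  res <- exact_toy(c(5L, 7L), c(40L, 38L), phi = 0.05)
  expect_equal(res$pvalue, oracle_cond_exact_p(c(5, 7), c(40, 38), 0.05),
               tolerance = 1e-10)
  set.seed(99)
  for (i in 1:8) {
    nA <- sample(2:3, 1); nB <- sample(2:3, 1)
    ca <- rpois(nA, 20); cb <- rpois(nB, 35)
    if (sum(ca, cb) > 200) next
    phi <- runif(1, 0.01, 0.5)
    res <- exact_toy(as.integer(ca), as.integer(cb), phi, total = 250L)
    expect_equal(res$pvalue, oracle_cond_exact_p(ca, cb, phi),
                 tolerance = 1e-10)
  }
})

test_that("unknown taxa and missing replication are rejected", {
  y <- make_matrix(matrix(5L, 4, 4))
  samples <- data.frame(sample = paste0("s", 1:4),
                        taxon = c("A", "A", "B", "B"), replicate = c(1:2, 1:2))
  expect_error(nb_exact_test(y, samples, "A", "C", 0.1), "unknown taxon")
  samples2 <- data.frame(sample = paste0("s", 1:4),
                         taxon = c("A", "A", "A", "B"), replicate = c(1:3, 1))
  expect_error(nb_exact_test(y, samples2, "A", "B", 0.1), "replicates")
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(p), c(0.04, 0.04, 4 * 0.04 / 3, 0.8))
  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is monotone on sorted input and bounded by [p, 1]", {
  set.seed(5)
  p <- sort(runif(40))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
})

test_that("DE calls use strict q < alpha and no fold-change cutoff", {
  res <- data.frame(locus = c("a", "b", "c"),
                    logFC = c(1, -5, 0.1),
                    pvalue = c(0.001, 0.01, 0.04),
                    qvalue = c(0.049, 0.2, 0.05))
  out <- call_de(res, alpha = 0.05)
  expect_identical(out$de_flag, c(TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("up_in_second", "none", "none"))
  expect_error(call_de(res, alpha = 1.2), "alpha")
})

test_that("called-DE fraction grows with simulated effect size", {
  frac <- sapply(c(1e-6, 1, 2), function(eff) {
    cfg <- sim_config(600, seed = 77, taxa = c("bro", "fru"),
                      phenotype_fractions = c(parental_de = 0.2),
                      effect_size = eff)
    sim <- simulate_counts(cfg)
    dr <- run_pairwise_de(sim$counts, sim$samples)
    mean(dr$de$bro_fru$de_flag)
  })
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.02)
  expect_gt(frac[3], 0.1)
})
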