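test_that("hit-table parsing round-trips and validates", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("x|t1\ty|t2\t98.5\t300\t4\t0\t1\t300\t1\t300\t1e-50\t550.5", tmp)
  h <- parse_hit_table(tmp)
  expect_identical(nrow(h), 1L)
  expect_equal(h$bitscore, 550.5)
  expect_equal(h$evalue, 1e-50)

  writeLines(character(0), tmp)
  expect_identical(nrow(parse_hit_table(tmp)), 0L)

  ht <- random_hit_table(100, seed = 8)
  write_hit_table(ht, tmp)
  back <- parse_hit_table(tmp)
  expect_equal(back, ht, tolerance = 1e-12)

  writeLines("a\tb\tc", tmp)
  expect_error(parse_hit_table(tmp), "line 1")
  writeLines("x\ty\tbad\t300\t4\t0\t1\t300\t1\t300\t1e-50\t550", tmp)
  expect_error(parse_hit_table(tmp), "unparseable")
})

test_that("reciprocal best hits require mutual bests", {
  h <- rbind(
    data.frame(qseqid = "X|1", sseqid = "Y|1", bitscore = 100),
    data.frame(qseqid = "Y|1", sseqid = "X|1", bitscore = 90))
  h <- cbind(h, pident = 99, length = 100L, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = 1e-30)
  p <- reciprocal_best_hits(h, "X", "Y")
  expect_identical(p$a, "X|1")

  # X|1's best is Y|1 but Y|1's best is X|2: no pair
  h2 <- rbind(h, data.frame(qseqid = "Y|1", sseqid = "X|2", bitscore = 95,
                            pident = 99, length = 100L, mismatch = 0L,
                            gapopen = 0L, qstart = 1L, qend = 100L,
                            sstart = 1L, send = 100L, evalue = 1e-30))
  expect_identical(nrow(reciprocal_best_hits(h2, "X", "Y")), 0L)

  expect_warning(reciprocal_best_hits(h[1, ], "X", "Y"), "direction")
})

test_that("RBBH matches all-pairs brute-force enumeration on random tables", {
  for (seed in 1:30) {
    h <- random_hit_table(60, seed = seed)
    mine <- reciprocal_best_hits(h, "X", "Y")
    ref <- oracle_rbbh(h, "X", "Y")
    expect_identical(mine$a, ref$a)
    expect_identical(mine$b, ref$b)
  }
})

test_that("RBBH is symmetric in the two taxa", {
  for (seed in c(2, 17)) {
    h <- random_hit_table(80, seed = seed)
    xy <- reciprocal_best_hits(h, "X", "Y")
    yx <- reciprocal_best_hits(h, "Y", "X")
    expect_setequal(paste(xy$a, xy$b), paste(yx$b, yx$a))
  }
})

test_that("pair DE classification follows the two members' flags", {
  de <- data.frame(locus = c("X|1", "Y|1", "X|2", "Y|2", "X|3", "Y|3"),
                   logFC = c(-2, 2, -1, -1, -3, 0.1),
                   pvalue = 0.001,
                   qvalue = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.8))
  de <- call_de(de)
  pairs <- data.frame(a = c("X|1", "X|2", "X|3"), b = c("Y|1", "Y|2", "Y|3"),
                      bitscore_fwd = 1, bitscore_rev = 1)
  cl <- classify_pairs_de(pairs, de)
  expect_identical(cl$category, c("both", "both", "one"))
  expect_identical(cl$relation, c("reciprocal", "same_direction", NA))
  bad <- data.frame(a = "X|9", b = "Y|1", bitscore_fwd = 1, bitscore_rev = 1)
  expect_error(classify_pairs_de(bad, de), "X\\|9")
})

test_that("chi-squared report matches the direct formula", {
  cl <- rbind(make_classes(10, 10),
              data.frame(a = paste0("X|o", 1:20), b = paste0("Y|o", 1:20),
                         de_a = TRUE, de_b = FALSE, logFC_a = 1, logFC_b = 0,
                         category = "one", relation = NA),
              data.frame(a = paste0("X|n", 1:60), b = paste0("Y|n", 1:60),
                         de_a = FALSE, de_b = FALSE, logFC_a = 0, logFC_b = 0,
                         category = "neither", relation = NA))
  rep <- coassembly_chi2(cl)
  p_hat <- (2 * 20 + 20) / 200
  expected <- 100 * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  chi2 <- sum((c(20, 20, 60) - expected)^2 / expected)
  expect_equal(rep$chi2, chi2)
  expect_equal(rep$phi, sqrt(chi2 / 100))
  expect_equal(rep$p_value, pchisq(chi2, 1, lower.tail = FALSE))
  expect_true(rep$defined)
  expect_equal(sum(rep$observed), 100)
  expect_equal(sum(rep$expected), 100, tolerance = 1e-9)
})

test_that("degenerate marginals flag the test as undefined", {
  cl <- data.frame(a = "X|1", b = "Y|1", de_a = FALSE, de_b = FALSE,
                   logFC_a = 0, logFC_b = 0, category = "neither",
                   relation = NA)
  rep <- coassembly_chi2(cl)
  expect_false(rep$defined)
  expect_true(is.na(rep$phi))
})

test_that("chi-squared p-values are calibrated under independent DE flags", {
  set.seed(314)
  n <- 10000
  rej <- vapply(1:200, function(i) {
    fa <- runif(n) < 0.1
    fb <- runif(n) < 0.1
    cl <- data.frame(a = paste0("X|", 1:n), b = paste0("Y|", 1:n),
                     de_a = fa, de_b = fb,
                     logFC_a = ifelse(fa, 1, 0), logFC_b = ifelse(fb, 1, 0),
                     category = ifelse(fa & fb, "both",
                                       ifelse(fa | fb, "one", "neither")),
                     relation = NA)
    coassembly_chi2(cl)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("expected reciprocal fraction is 2q(1-q)", {
  expect_equal(expected_reciprocal_fraction(7, 1), 0.21875)
  expect_identical(round(100 * expected_reciprocal_fraction(7, 1)), 22)
  expect_equal(expected_reciprocal_fraction(1, 1), 0.5)
  expect_equal(expected_reciprocal_fraction(5, 0), 0)
  expect_error(expected_reciprocal_fraction(0, 0), "at least one")
})

test_that("direction partition reproduces printed worked examples", {
  dr <- direction_partition(make_classes(18, 75))
  expect_equal(round(100 * dr$observed_fraction, 1), 19.4)
  expect_identical(dr$n_reciprocal, 18L)

  cl <- make_classes(1, 3)      # members 7 up vs 1 down
  dr2 <- direction_partition(cl)
  expect_equal(dr2$q_hat, 7 / 8)
  expect_equal(100 * dr2$observed_fraction, 25)
  expect_equal(100 * dr2$expected_fraction, 21.875)

  all_same <- direction_partition(make_classes(0, 5))
  expect_equal(all_same$observed_fraction, 0)
  expect_error(direction_partition(make_classes(0, 5)[0, ]), "both-DE")
})

test_that("pipeline comparison table prints study-style percentages", {
  rep <- pipeline_comparison_report(list(
    p1 = list(n_loci = 794264, n_de = 16834),
    p5 = list(n_loci = 37256, n_de = 2786,
              direction = direction_partition(make_classes(18, 75))),
    p0 = list(n_loci = 100, n_de = 0,
              contingency = coassembly_chi2(
                data.frame(a = "X|1", b = "Y|1", de_a = FALSE, de_b = FALSE,
                           logFC_a = 0, logFC_b = 0, category = "neither",
                           relation = NA)))))
  expect_equal(rep$pct_de, c(2.12, 7.48, 0))
  expect_equal(rep$pct_reciprocal[2], 19.4)
  expect_equal(rep$pct_same[2], 80.6)
  expect_false(rep$chi2_defined[3])
})
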