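test_that("single-locus classification matches the truth-table rows", {
  # parental DE with sun tracking bro: DE in bro-fru and fru-sun only
  lab <- classify_locus(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_setequal(lab, c("parental_de", "sun_bro_like"))

  expect_identical(classify_locus(rep(FALSE, 6)), character(0))

  lab2 <- classify_locus(rep(TRUE, 6))
  expect_setequal(lab2, c("parental_de", "novel_sun", "novel_lem",
                          "hybrid_de"))
  expect_error(classify_locus(c(TRUE, NA, TRUE, TRUE, TRUE, TRUE)),
               "six")
})

test_that("all 64 flag patterns agree with the independent row oracle", {
  rules <- phenotype_rules()
  for (code in 0:63) {
    flags <- as.logical(bitwAnd(code, 2^(0:5)) > 0)
    expect_setequal(classify_locus(flags, rules), oracle_classify(flags))
  }
})

test_that("parent-like matches imply a parental-DE match", {
  rules <- phenotype_rules()
  c_rows <- names(rules$type)[rules$type == "C"]
  for (code in 0:63) {
    flags <- as.logical(bitwAnd(code, 2^(0:5)) > 0)
    lab <- classify_locus(flags, rules)
    if (any(lab %in% c_rows)) expect_true("parental_de" %in% lab)
  }
})

test_that("precedence yields exactly one disjoint label per matching locus", {
  rules <- phenotype_rules()
  flag_mat <- t(vapply(0:63, function(code)
    as.logical(bitwAnd(code, 2^(0:5)) > 0), logical(6)))
  rownames(flag_mat) <- paste0("P", 0:63)
  colnames(flag_mat) <- rules$comparisons
  mm <- orthoDE:::match_rules(flag_mat, rules)
  lab <- orthoDE:::resolve_disjoint(mm, rules)
  matched_any <- rowSums(mm[, rules$precedence, drop = FALSE]) > 0
  expect_identical(!is.na(lab), unname(matched_any))
  expect_true(all(lab[!is.na(lab)] %in% rules$precedence))
  # shared categories beat species-specific ones
  shared <- flag_mat[, 1] & !flag_mat[, 2] & !flag_mat[, 3] &
    flag_mat[, 4] & flag_mat[, 5] & !flag_mat[, 6]
  expect_true(all(lab[shared] == "both_bro_like"))
})

test_that("novel modes follow the ordering of hybrid and parent means", {
  expect_identical(annotate_novel_mode(c(bro = 10, fru = 20, sun = 35), "sun"),
                   "transgressive_up")
  expect_identical(annotate_novel_mode(c(bro = 10, fru = 20, sun = 15), "sun"),
                   "intermediate")
  expect_identical(annotate_novel_mode(c(bro = 10, fru = 20, sun = 4), "sun"),
                   "transgressive_down")
  expect_error(annotate_novel_mode(c(bro = 10, sun = 4), "sun"), "fru")
})

test_that("novel totals and parent-bias ratios match the printed accounting", {
  counts <- c(parental_de = 2786, novel_sun = 14, novel_lem = 11,
              novel_both = 33, sun_bro_like = 482, sun_fru_like = 464,
              lem_bro_like = 657, lem_fru_like = 407, both_bro_like = 261,
              both_fru_like = 198, hybrid_de = 129)
  expect_identical(novel_total(counts), 58)

  bias_sun <- parent_bias_summary(counts, "sun")
  expect_identical(bias_sun$n_first_like, 743)
  expect_identical(bias_sun$n_second_like, 662)
  expect_identical(bias_sun$ratio, "53:47")

  bias_lem <- parent_bias_summary(counts, "lem")
  expect_identical(bias_lem$n_first_like, 918)
  expect_identical(bias_lem$n_second_like, 605)
  expect_identical(bias_lem$ratio, "60:40")

  zero <- counts * 0
  expect_false(parent_bias_summary(zero, "sun")$defined)
  expect_identical(novel_total(zero), 0)
})

test_that("classify_all validates inputs and handles empty sets", {
  rules <- phenotype_rules()
  de <- lapply(rules$comparisons, function(nm)
    data.frame(locus = c("l1", "l2"), logFC = 0, pvalue = 1, qvalue = 1,
               de_flag = FALSE, direction = "none"))
  names(de) <- rules$comparisons
  out <- classify_all(de, rules = rules)
  expect_identical(sum(out$counts$n), 0L)

  de_bad <- de
  de_bad[[1]] <- de_bad[[1]][1, ]
  expect_error(classify_all(de_bad, rules = rules), "locus set")

  de0 <- lapply(de, function(d) d[0, ])
  out0 <- classify_all(de0, rules = rules)
  expect_identical(nrow(out0$calls), 0L)
  expect_true(all(out0$counts$n == 0))
})

# study-style category accounting re-derived from a loci x 6 flag matrix,
# using the independently coded row matcher
oracle_phenotype_counts <- function(flag_mat) {
  labs <- apply(flag_mat, 1, oracle_classify)
  has <- function(row) vapply(labs, function(x) row %in% x, logical(1))
  c(parental_de = sum(has("parental_de")),
    novel_sun = sum(has("novel_sun")),
    novel_lem = sum(has("novel_lem")),
    novel_both = sum(has("novel_both")),
    sun_bro_like = sum(has("sun_bro_like") & !has("both_bro_like")),
    sun_fru_like = sum(has("sun_fru_like") & !has("both_fru_like")),
    lem_bro_like = sum(has("lem_bro_like") & !has("both_bro_like")),
    lem_fru_like = sum(has("lem_fru_like") & !has("both_fru_like")),
    both_bro_like = sum(has("both_bro_like")),
    both_fru_like = sum(has("both_fru_like")),
    hybrid_de = sum(has("hybrid_de")))
}

test_that("simulated phenotype classes are recovered at strong effects", {
  frac <- c(parental_de = 0.06, sun_bro_like = 0.02, sun_fru_like = 0.02,
            lem_bro_like = 0.02, lem_fru_like = 0.02, both_bro_like = 0.02,
            both_fru_like = 0.02, novel_sun = 0.01, novel_lem = 0.01,
            novel_both = 0.01)
  cfg <- sim_config(2500, seed = 101, phenotype_fractions = frac,
                    effect_size = 3)
  sim <- simulate_counts(cfg)
  dr <- run_pairwise_de(sim$counts, sim$samples)
  rules <- phenotype_rules()
  cpm <- cpm_matrix(sim$counts, dr$factors)
  gm <- vapply(cfg$taxa, function(tx)
    rowMeans(cpm[, sim$samples$sample[sim$samples$taxon == tx]]),
    numeric(nrow(cpm)))
  out <- classify_all(dr$de[rules$comparisons], gm, rules)

  # truth-implied category counts: true flags from the true means, run
  # through the independent row-matching oracle and the same accounting
  pair_idx <- list(c("bro", "fru"), c("bro", "sun"), c("bro", "lem"),
                   c("fru", "sun"), c("fru", "lem"), c("sun", "lem"))
  true_flags <- vapply(pair_idx, function(p)
    abs(log2(sim$truth[[paste0("mean_", p[2])]] /
               sim$truth[[paste0("mean_", p[1])]])) > 1e-9,
    logical(nrow(sim$truth)))
  implied <- oracle_phenotype_counts(true_flags)
  called <- setNames(out$counts$n, out$counts$phenotype)
  for (cat in names(implied)) {
    p_cat <- implied[[cat]] / 2500
    tol <- 3 * sqrt(2500 * p_cat * (1 - p_cat)) + 3
    expect_lt(abs(called[[cat]] - implied[[cat]]), tol,
              label = sprintf("category %s (called %d, implied %d)",
                              cat, called[[cat]], implied[[cat]]))
  }

  # simulated novel loci are transgressive and annotated as such
  novel_truth <- sim$truth$transcript_id[sim$truth$label %in%
                                           c("novel_sun", "novel_both")]
  called_novel <- out$calls[out$calls$locus %in% novel_truth &
                              out$calls$novel_mode_sun != "not_applicable", ]
  expect_gt(nrow(called_novel), 0)
  expect_true(all(called_novel$novel_mode_sun %in%
                    c("transgressive_up", "transgressive_down")))
})
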