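#' Expression-phenotype truth table
#'
#' The classification rules over the six pairwise DE comparisons of two
#' parents (p1, p2) and two hybrids (h1, h2), in the fixed comparison order
#' (p1,p2), (p1,h1), (p1,h2), (p2,h1), (p2,h2), (h1,h2). Each rule cell is
#' `TRUE` (must be DE), `FALSE` (must not be DE) or `NA` (either pattern).
#' Row types: A = DE between the parents; B = novel expression in one or
#' both hybrids; C = parent-like expression in one or both hybrids (always
#' on top of parental DE); D = DE between the two hybrids.
#'
#' @param parents,hybrids taxon labels.
#' @return list with `rules` (11 x 6 logical matrix, NA = unconstrained),
#'   `type` (A/B/C/D per row), `comparisons` (the six comparison names) and
#'   `precedence` (label order used to resolve overlapping matches into a
#'   single disjoint label; shared hybrid categories before species-specific
#'   ones, B/C before bare A, D kept out and reported independently).
#' @export
phenotype_rules <- function(parents = c("bro", "fru"),
                            hybrids = c("sun", "lem")) {
  p1 <- parents[1]; p2 <- parents[2]; h1 <- hybrids[1]; h2 <- hybrids[2]
  cmp <- c(paste(p1, p2, sep = "_"), paste(p1, h1, sep = "_"),
           paste(p1, h2, sep = "_"), paste(p2, h1, sep = "_"),
           paste(p2, h2, sep = "_"), paste(h1, h2, sep = "_"))
  Y <- TRUE; N <- FALSE; . <- NA
  rules <- rbind(
    parental_de = c(Y, ., ., ., ., .),
    novel_h1    = c(., Y, ., Y, ., Y),
    novel_h2    = c(., ., Y, ., Y, Y),
    novel_both  = c(., Y, Y, Y, Y, N),
    h1_p1_like  = c(Y, N, ., Y, ., .),
    h1_p2_like  = c(Y, Y, ., N, ., .),
    h2_p1_like  = c(Y, ., N, ., Y, .),
    h2_p2_like  = c(Y, ., Y, ., N, .),
    both_p1_like = c(Y, N, N, Y, Y, N),
    both_p2_like = c(Y, Y, Y, N, N, N),
    hybrid_de   = c(., ., ., ., ., Y))
  rownames(rules) <- c("parental_de",
                       paste0("novel_", h1), paste0("novel_", h2),
                       "novel_both",
                       paste0(h1, "_", p1, "_like"),
                       paste0(h1, "_", p2, "_like"),
                       paste0(h2, "_", p1, "_like"),
                       paste0(h2, "_", p2, "_like"),
                       paste0("both_", p1, "_like"),
                       paste0("both_", p2, "_like"),
                       "hybrid_de")
  colnames(rules) <- cmp
  type <- c("A", "B", "B", "B", "C", "C", "C", "C", "C", "C", "D")
  names(type) <- rownames(rules)
  precedence <- c("novel_both",
                  paste0("both_", p1, "_like"), paste0("both_", p2, "_like"),
                  paste0("novel_", h1), paste0("novel_", h2),
                  paste0(h1, "_", p1, "_like"), paste0(h1, "_", p2, "_like"),
                  paste0(h2, "_", p1, "_like"), paste0(h2, "_", p2, "_like"),
                  "parental_de")
  list(rules = rules, type = type, comparisons = cmp, precedence = precedence,
       parents = parents, hybrids = hybrids)
}

#' Classify one locus's six DE flags against the truth table
#'
#' A label matches iff every must-be-DE cell of its row is TRUE and every
#' must-not-be-DE cell is FALSE; unconstrained cells are ignored. All
#' matching labels are returned.
#'
#' @param flags logical vector of six DE indicators in the fixed comparison
#'   order.
#' @param rules a [phenotype_rules()] object.
#' @return character vector of matched labels (possibly empty).
#' @export
classify_locus <- function(flags, rules = phenotype_rules()) {
  if (length(flags) != 6 || anyNA(flags))
    stopf("'flags' must be six non-missing booleans")
  R <- rules$rules
  ok <- vapply(seq_len(nrow(R)), function(i) {
    req <- R[i, ]
    all(flags[!is.na(req)] == req[!is.na(req)])
  }, logical(1))
  rownames(R)[ok]
}

# vectorized matcher: loci x labels logical match matrix
match_rules <- function(flag_mat, rules) {
  R <- rules$rules
  out <- matrix(TRUE, nrow(flag_mat), nrow(R),
                dimnames = list(rownames(flag_mat), rownames(R)))
  for (i in seq_len(nrow(R))) {
    req <- R[i, ]
    j <- which(!is.na(req))
    out[, i] <- rowSums(flag_mat[, j, drop = FALSE] ==
                          matrix(req[j], nrow(flag_mat), length(j),
                                 byrow = TRUE)) == length(j)
  }
  out
}

resolve_disjoint <- function(match_mat, rules) {
  lab <- rep(NA_character_, nrow(match_mat))
  for (p in rev(rules$precedence)) lab[match_mat[, p]] <- p
  lab
}

#' Annotate a novel locus as transgressive or intermediate
#'
#' A hybrid's expression is transgressive when its group mean lies above the
#' larger (or below the smaller) of the two parental means, and intermediate
#' otherwise. Means are TMM-normalized CPM group means.
#'
#' @param means named numeric vector of per-taxon group means for one locus.
#' @param hybrid the hybrid taxon.
#' @param parents the two parent taxa.
#' @return `"transgressive_up"`, `"transgressive_down"` or
#'   `"intermediate"`.
#' @export
annotate_novel_mode <- function(means, hybrid, parents = c("bro", "fru")) {
  need <- c(hybrid, parents)
  if (!all(need %in% names(means)))
    stopf("missing taxon mean(s): %s",
          paste(setdiff(need, names(means)), collapse = ", "))
  h <- means[[hybrid]]
  pm <- unlist(means[parents])
  if (h > max(pm)) "transgressive_up"
  else if (h < min(pm)) "transgressive_down"
  else "intermediate"
}

#' Classify all loci from the six pairwise DE tables
#'
#' Builds the six-flag pattern per locus, matches the truth table, resolves
#' a single disjoint label by precedence (shared hybrid categories over
#' species-specific ones over bare parental DE) for the per-locus calls,
#' annotates loci with novel labels as transgressive/intermediate per
#' hybrid, and tallies a category-count table.
#'
#' The count table follows the study-style accounting: the parental-DE (A)
#' and hybrid-hybrid-DE (D) rows are marginal row-match counts, while the
#' novel (B) and parent-like (C) rows are disjoint — a species-specific
#' parent-like row excludes loci that also match the same parent's shared
#' row, so that species-specific and shared counts are additive per hybrid.
#' Loci novel in both hybrids via all-six-DE patterns are counted in each
#' hybrid's novel row and flagged `multi_specific_novel`.
#'
#' @param de_list named list of six called DE tables whose names are the
#'   comparison names of `rules$comparisons`.
#' @param group_means optional loci x taxa matrix of normalized group means
#'   (required for novel-mode annotation).
#' @param rules a [phenotype_rules()] object.
#' @return list with `calls` (per-locus data.frame) and `counts`
#'   (data.frame type / phenotype / n, in truth-table row order).
#' @export
classify_all <- function(de_list, group_means = NULL,
                         rules = phenotype_rules()) {
  cmp <- rules$comparisons
  if (!all(cmp %in% names(de_list)))
    stopf("missing DE table(s): %s",
          paste(setdiff(cmp, names(de_list)), collapse = ", "))
  loci <- de_list[[cmp[1]]]$locus
  flag_mat <- matrix(NA, length(loci), length(cmp),
                     dimnames = list(loci, cmp))
  for (nm in cmp) {
    d <- de_list[[nm]]
    i <- match(loci, d$locus)
    if (anyNA(i) || nrow(d) != length(loci))
      stopf("DE table '%s' does not cover the same locus set (e.g. %s)", nm,
            paste(utils::head(c(loci[is.na(i)],
                                setdiff(d$locus, loci)), 3), collapse = ", "))
    flag_mat[, nm] <- d$de_flag[i]
  }
  if (!length(loci)) {
    counts <- data.frame(type = unname(rules$type),
                         phenotype = names(rules$type), n = 0L,
                         stringsAsFactors = FALSE)
    return(list(calls = data.frame(locus = character(0)), counts = counts))
  }
  mm <- match_rules(flag_mat, rules)
  disjoint <- resolve_disjoint(mm, rules)
  hybrids <- rules$hybrids
  multi_specific <- mm[, paste0("novel_", hybrids[1])] &
    mm[, paste0("novel_", hybrids[2])]

  calls <- data.frame(locus = loci, stringsAsFactors = FALSE)
  calls <- cbind(calls, as.data.frame(flag_mat))
  calls$matched <- apply(mm, 1, function(r)
    paste(colnames(mm)[r], collapse = ";"))
  calls$label <- disjoint
  calls$hybrid_de <- mm[, "hybrid_de"]
  calls$multi_specific_novel <- multi_specific
  for (h in hybrids) {
    col <- paste0("novel_mode_", h)
    calls[[col]] <- "not_applicable"
    novel_h <- mm[, paste0("novel_", h)] | mm[, "novel_both"]
    if (any(novel_h)) {
      if (is.null(group_means))
        stopf("'group_means' required to annotate novel loci")
      calls[[col]][novel_h] <- vapply(which(novel_h), function(i)
        annotate_novel_mode(as.list(group_means[loci[i], ]), h,
                            rules$parents), "")
    }
  }
  n_cat <- vapply(names(rules$type), function(lb) {
    tp <- rules$type[[lb]]
    if (tp %in% c("A", "D") || startsWith(lb, "novel_"))
      return(sum(mm[, lb]))
    if (startsWith(lb, "both_")) return(sum(mm[, lb]))
    # species-specific parent-like: exclude the same parent's shared row
    shared <- sub("^[^_]+_", "both_", lb)
    sum(mm[, lb] & !mm[, shared])
  }, integer(1))
  counts <- data.frame(type = unname(rules$type),
                       phenotype = names(rules$type),
                       n = unname(n_cat), stringsAsFactors = FALSE)
  list(calls = calls, counts = counts)
}

category_counts <- function(counts) {
  if (is.data.frame(counts)) stats::setNames(counts$n, counts$phenotype)
  else counts
}

#' Total loci with novel expression
#'
#' Sum of the three novel disjoint categories (novel in the first hybrid,
#' the second, or both).
#'
#' @param counts a category-count table from [classify_all()] (or a named
#'   vector of category counts).
#' @param hybrids hybrid taxon labels.
#' @return integer total.
#' @export
novel_total <- function(counts, hybrids = c("sun", "lem")) {
  n <- category_counts(counts)
  cats <- c(paste0("novel_", hybrids), "novel_both")
  missing <- setdiff(cats, names(n))
  if (length(missing))
    stopf("missing novel categories: %s", paste(missing, collapse = ", "))
  sum(n[cats])
}

#' Combined parent-bias summary for one hybrid
#'
#' Adds the hybrid's species-specific parent-like counts to the shared
#' parent-like counts, and reports the totals with a rounded percent ratio
#' (nearest integer, complement forced to 100).
#'
#' @param counts a category-count table from [classify_all()] (or a named
#'   vector of category counts).
#' @param hybrid the hybrid taxon.
#' @param parents the two parent taxa.
#' @return list with `n_first_like`, `n_second_like`, `ratio` (e.g.
#'   `"53:47"`, NA with `defined = FALSE` when both totals are zero).
#' @export
parent_bias_summary <- function(counts, hybrid, parents = c("bro", "fru")) {
  n <- category_counts(counts)
  need <- c(paste0(hybrid, "_", parents, "_like"),
            paste0("both_", parents, "_like"))
  missing <- setdiff(need, names(n))
  if (length(missing))
    stopf("missing categories: %s", paste(missing, collapse = ", "))
  n1 <- unname(n[need[1]] + n[need[3]])
  n2 <- unname(n[need[2]] + n[need[4]])
  if (n1 + n2 == 0)
    return(list(hybrid = hybrid, n_first_like = 0, n_second_like = 0,
                ratio = NA_character_, defined = FALSE))
  p <- round(100 * n1 / (n1 + n2))
  list(hybrid = hybrid, n_first_like = n1, n_second_like = n2,
       ratio = paste0(p, ":", 100 - p), defined = TRUE)
}
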