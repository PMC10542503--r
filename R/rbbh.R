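hit_table_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

empty_hit_table <- function() {
  out <- data.frame(qseqid = character(0), sseqid = character(0),
                    pident = numeric(0), length = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Parse a BLAST tabular (outfmt 6) hit table
#'
#' Expects at least the 12 standard tab-separated columns (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore);
#' extra columns are ignored. Malformed lines raise an error naming the
#' line number.
#'
#' @param path file path (or connection readable by [readLines()]).
#' @return data.frame of class `hit_table`, one row per hit.
#' @export
parse_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12))
    stopf("hit table line %d has %d columns, expected >= 12",
          which(nc < 12)[1], nc[nc < 12][1])
  m <- t(vapply(parts, function(x) x[1:12], character(12)))
  num <- function(col, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stopf("hit table line %d: unparseable %s '%s'",
            which(is.na(v))[1], what, m[which(is.na(v))[1], col])
    if (integer) as.integer(v) else v
  }
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = num(3, "pident"),
                    length = num(4, "length", TRUE),
                    mismatch = num(5, "mismatch", TRUE),
                    gapopen = num(6, "gapopen", TRUE),
                    qstart = num(7, "qstart", TRUE),
                    qend = num(8, "qend", TRUE),
                    sstart = num(9, "sstart", TRUE),
                    send = num(10, "send", TRUE),
                    evalue = num(11, "evalue"),
                    bitscore = num(12, "bitscore"),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$qseqid)) || any(!nzchar(out$sseqid)))
    stopf("hit table contains empty sequence ids")
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write a hit table in BLAST tabular layout
#'
#' @param hits a `hit_table` data.frame.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Taxon of a transcript id
#'
#' Default id convention: the taxon (or lineage) label is the prefix before
#' the first `|`.
#'
#' @param ids character vector of transcript ids.
#' @return character vector of taxon labels.
#' @export
id_taxon <- function(ids) sub("\\|.*$", "", ids)

# best hit per query: max bitscore, ties by lower e-value, longer
# alignment, then lexicographic subject id
best_per_query <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$length,
             hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two taxa
#'
#' For each query transcript the best hit is the maximum-bitscore subject
#' (ties broken by lower e-value, then longer alignment, then lexicographic
#' subject id); multiple HSPs for a query/subject pair are collapsed to the
#' best-scoring one first. A pair is kept iff each member is the other's
#' best hit. Output is sorted by the first member's id.
#'
#' @param hits a `hit_table`.
#' @param taxon_x,taxon_y the two taxon labels.
#' @param taxon_fun function mapping transcript ids to taxon labels
#'   (default [id_taxon()]).
#' @return data.frame with columns a, b, bitscore_fwd, bitscore_rev.
#' @export
reciprocal_best_hits <- function(hits, taxon_x, taxon_y,
                                 taxon_fun = id_taxon) {
  qt <- taxon_fun(hits$qseqid)
  st <- taxon_fun(hits$sseqid)
  fwd <- hits[qt == taxon_x & st == taxon_y, , drop = FALSE]
  rev <- hits[qt == taxon_y & st == taxon_x, , drop = FALSE]
  empty <- data.frame(a = character(0), b = character(0),
                      bitscore_fwd = numeric(0), bitscore_rev = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(fwd) || !nrow(rev)) {
    warnf("no hits in the %s direction; returning no pairs",
          if (nrow(fwd)) paste(taxon_y, "->", taxon_x)
          else paste(taxon_x, "->", taxon_y))
    return(empty)
  }
  bf <- best_per_query(fwd)
  br <- best_per_query(rev)
  back <- stats::setNames(br$sseqid, br$qseqid)
  mutual <- !is.na(back[bf$sseqid]) & back[bf$sseqid] == bf$qseqid
  bf <- bf[mutual, , drop = FALSE]
  if (!nrow(bf)) return(empty)
  br_bit <- stats::setNames(br$bitscore, br$qseqid)
  out <- data.frame(a = bf$qseqid, b = bf$sseqid,
                    bitscore_fwd = bf$bitscore,
                    bitscore_rev = unname(br_bit[bf$sseqid]),
                    stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

#' Cross-tabulate the DE status of RBBH pairs
#'
#' Looks both members of each pair up in a DE table (for the parental
#' comparison) and classifies the pair as both / one / neither DE; for
#' both-DE pairs the relation is `reciprocal` when the two fold changes have
#' opposite signs and `same_direction` otherwise.
#'
#' @param pairs output of [reciprocal_best_hits()].
#' @param de a called DE table ([call_de()]) covering both members.
#' @return data.frame with the pair, per-member flags and directions,
#'   `category` and `relation` (NA unless both DE).
#' @export
classify_pairs_de <- function(pairs, de) {
  look <- function(ids, col) {
    i <- match(ids, de$locus)
    if (anyNA(i))
      stopf("transcript(s) missing from the DE table: %s",
            paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
    de[[col]][i]
  }
  fa <- look(pairs$a, "de_flag"); fb <- look(pairs$b, "de_flag")
  la <- look(pairs$a, "logFC"); lb <- look(pairs$b, "logFC")
  category <- ifelse(fa & fb, "both", ifelse(fa | fb, "one", "neither"))
  relation <- ifelse(category != "both", NA_character_,
                     ifelse(sign(la) * sign(lb) < 0, "reciprocal",
                            "same_direction"))
  data.frame(a = pairs$a, b = pairs$b, de_a = fa, de_b = fb,
             logFC_a = la, logFC_b = lb,
             category = category, relation = relation,
             stringsAsFactors = FALSE)
}

#' Chi-squared / phi test of RBBH DE-status association
#'
#' Tests whether the (both, one, neither)-DE counts among N RBBH pairs
#' deviate from independence of the two members' DE status. By default the
#' marginal DE rate is estimated from the 2N pair members themselves
#' (`marginal = "members"`) and the test has 1 df (three cells, one
#' estimated parameter); alternatively an external (e.g. transcriptome-wide)
#' DE rate can be supplied, with 2 df. The effect size is
#' `phi = sqrt(chi2 / N)`.
#'
#' @param classes output of [classify_pairs_de()].
#' @param marginal `"members"` or `"external"`.
#' @param external_rate marginal DE rate when `marginal = "external"`.
#' @param df degrees of freedom (default 1 for the members null, 2 for the
#'   external null).
#' @return list of class `contingency_report`: N, observed and expected
#'   counts, p_hat, chi2, df, p_value, phi, and `defined` (FALSE when the
#'   marginal rate is degenerate, in which case the test fields are NA).
#' @export
coassembly_chi2 <- function(classes, marginal = c("members", "external"),
                            external_rate = NULL, df = NULL) {
  marginal <- match.arg(marginal)
  N <- nrow(classes)
  if (N < 1) stopf("no RBBH pairs to test")
  obs <- c(both = sum(classes$category == "both"),
           one = sum(classes$category == "one"),
           neither = sum(classes$category == "neither"))
  p_hat <- if (marginal == "members") (2 * obs[["both"]] + obs[["one"]]) / (2 * N)
           else {
             if (is.null(external_rate)) stopf("'external_rate' required")
             external_rate
           }
  if (is.null(df)) df <- if (marginal == "members") 1 else 2
  expected <- N * c(both = p_hat^2, one = 2 * p_hat * (1 - p_hat),
                    neither = (1 - p_hat)^2)
  out <- list(n_pairs = N, observed = obs, expected = expected,
              p_hat = p_hat, marginal = marginal, df = df,
              chi2 = NA_real_, p_value = NA_real_, phi = NA_real_,
              defined = FALSE)
  if (p_hat > 0 && p_hat < 1) {
    chi2 <- sum((obs - expected)^2 / expected)
    out$chi2 <- chi2
    out$p_value <- stats::pchisq(chi2, df, lower.tail = FALSE)
    out$phi <- sqrt(chi2 / N)
    out$defined <- TRUE
  }
  class(out) <- "contingency_report"
  out
}

#' @export
print.contingency_report <- function(x, ...) {
  cat(sprintf("RBBH DE contingency over %d pairs (marginal: %s, p_hat = %.4f)\n",
              x$n_pairs, x$marginal, x$p_hat))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  if (x$defined)
    cat(sprintf("chi2 = %.3f (df = %d), p = %.3g, phi = %.4f\n",
                x$chi2, x$df, x$p_value, x$phi))
  else cat("test undefined (degenerate marginal DE rate)\n")
  invisible(x)
}

#' Expected fraction of reciprocally DE pairs under independent directions
#'
#' If a fraction q of DE members is up in the first parent, and the two
#' members of a both-DE pair take directions independently, the expected
#' fraction of reciprocally DE pairs is 2q(1-q).
#'
#' @param n_up,n_down direction counts among the both-DE pair members.
#' @return the expected reciprocal fraction, in \[0, 0.5\].
#' @export
expected_reciprocal_fraction <- function(n_up, n_down) {
  if (n_up < 0 || n_down < 0) stopf("counts must be non-negative")
  if (n_up + n_down < 1) stopf("need at least one directed member")
  q <- n_up / (n_up + n_down)
  2 * q * (1 - q)
}

#' Partition both-DE RBBH pairs by direction
#'
#' Splits the both-DE pairs into reciprocally DE versus same-direction DE,
#' estimates the direction skew q (fraction of both-DE members up in the
#' first taxon), compares the observed reciprocal fraction with the 2q(1-q)
#' chance expectation, and attaches an exact binomial p-value for the
#' comparison (a formalization beyond the informal observed-vs-expected
#' reading; flagged in the output).
#'
#' @param classes output of [classify_pairs_de()].
#' @return list of class `direction_report`.
#' @export
direction_partition <- function(classes) {
  both <- classes[classes$category == "both", , drop = FALSE]
  if (!nrow(both)) stopf("no both-DE pairs")
  n_rec <- sum(both$relation == "reciprocal")
  n_same <- sum(both$relation == "same_direction")
  member_up_first <- c(both$logFC_a, both$logFC_b) < 0
  q_hat <- mean(member_up_first)
  expected <- 2 * q_hat * (1 - q_hat)
  p_value <- if (expected > 0 && expected < 1)
    stats::binom.test(n_rec, n_rec + n_same, p = expected)$p.value
  else NA_real_
  structure(list(n_reciprocal = n_rec, n_same = n_same,
                 observed_fraction = n_rec / (n_rec + n_same),
                 q_hat = q_hat, expected_fraction = expected,
                 binom_p = p_value,
                 note = "binomial test is an extension beyond the informal observed-vs-expected comparison"),
            class = "direction_report")
}

#' @export
print.direction_report <- function(x, ...) {
  cat(sprintf("both-DE RBBH pairs: %d reciprocal (%.1f%%), %d same direction (%.1f%%)\n",
              x$n_reciprocal, 100 * x$observed_fraction,
              x$n_same, 100 * (1 - x$observed_fraction)))
  cat(sprintf("direction skew q = %.4f; expected reciprocal fraction 2q(1-q) = %.4f\n",
              x$q_hat, x$expected_fraction))
  if (!is.na(x$binom_p))
    cat(sprintf("exact binomial p (observed vs expected) = %.3g\n", x$binom_p))
  invisible(x)
}

#' Pipeline comparison summary table
#'
#' One row per pipeline: number of loci, number and percentage DE (2
#' decimals), the chi-squared association of RBBH DE status with its p-value
#' and phi, and the reciprocal / same-direction partition counts with
#' percentages (1 decimal).
#'
#' @param pipelines named list; each element a list with `n_loci`, `n_de`,
#'   and optionally `contingency` (a `contingency_report`) and `direction`
#'   (a `direction_report`).
#' @return data.frame, one row per pipeline.
#' @export
pipeline_comparison_report <- function(pipelines) {
  if (!length(pipelines)) stopf("no pipelines given")
  rows <- lapply(names(pipelines), function(nm) {
    p <- pipelines[[nm]]
    ct <- p$contingency; dr <- p$direction
    data.frame(
      pipeline = nm,
      n_loci = p$n_loci,
      n_de = p$n_de,
      pct_de = round(100 * p$n_de / p$n_loci, 2),
      chi2 = if (!is.null(ct)) ct$chi2 else NA_real_,
      chi2_p = if (!is.null(ct)) ct$p_value else NA_real_,
      phi = if (!is.null(ct)) ct$phi else NA_real_,
      chi2_defined = if (!is.null(ct)) ct$defined else NA,
      n_reciprocal = if (!is.null(dr)) dr$n_reciprocal else NA_integer_,
      pct_reciprocal = if (!is.null(dr))
        round(100 * dr$observed_fraction, 1) else NA_real_,
      n_same = if (!is.null(dr)) dr$n_same else NA_integer_,
      pct_same = if (!is.null(dr))
        round(100 * (1 - dr$observed_fraction), 1) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
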