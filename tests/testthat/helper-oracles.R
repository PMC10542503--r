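# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive each quantity from first principles, by
# enumeration or direct formula, without calling the package's code paths.

# conditional two-sided exact p for the group-A sum, by convolving the
# per-replicate NB (or Poisson) pmfs up to the observed total
oracle_cond_exact_p <- function(counts_a, counts_b, phi) {
  s <- sum(counts_a, counts_b)
  sA <- sum(counts_a)
  nA <- length(counts_a); nB <- length(counts_b)
  m <- s / (nA + nB)
  pmf1 <- function(x) {
    if (phi > 0) stats::dnbinom(x, size = 1 / phi, mu = m)
    else stats::dpois(x, m)
  }
  base <- pmf1(0:s)
  conv_n <- function(n) {
    p <- base
    if (n >= 2) for (i in 2:n) {
      p <- vapply(0:s, function(z)
        sum(p[1:(z + 1)] * base[(z + 1):1]), numeric(1))
    }
    p
  }
  pA <- conv_n(nA)
  pB <- conv_n(nB)
  joint <- pA * rev(pB)          # P(SA = x) * P(SB = s - x), x = 0..s
  cond <- joint / sum(joint)
  lower <- sum(cond[1:(sA + 1)])
  upper <- sum(cond[(sA + 1):(s + 1)])
  min(1, 2 * min(lower, upper))
}

# BH step-up from the definition: q_(k) = min_{j >= k} min(1, n p_(j) / j)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, n * ps / seq_len(n))
  q <- rev(cummin(rev(raw)))
  out <- numeric(n)
  out[o] <- q
  out
}

# direct evaluation of the TMM formula for one sample against a reference
oracle_tmm_one <- function(obs, refc, trim_m = 0.30, trim_a = 0.05) {
  nO <- sum(obs); nR <- sum(refc)
  keep0 <- which(obs > 0 & refc > 0)
  o <- obs[keep0]; r <- refc[keep0]
  M <- log2((o / nO) / (r / nR))
  A <- 0.5 * log2((o / nO) * (r / nR))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  w <- 1 / ((nO - o) / (nO * o) + (nR - r) / (nR * r))
  2^(sum((w * M)[keep]) / sum(w[keep]))
}

# all-pairs mutual-best enumeration for RBBH, with the full tie-break chain
oracle_rbbh <- function(hits, taxon_x, taxon_y,
                        taxon_fun = function(id) sub("\\|.*$", "", id)) {
  better <- function(h1, h2) {
    # is hit row h1 strictly better than h2?
    if (h1$bitscore != h2$bitscore) return(h1$bitscore > h2$bitscore)
    if (h1$evalue != h2$evalue) return(h1$evalue < h2$evalue)
    if (h1$length != h2$length) return(h1$length > h2$length)
    h1$sseqid < h2$sseqid
  }
  best_map <- function(sub) {
    out <- list()
    for (i in seq_len(nrow(sub))) {
      h <- sub[i, ]
      cur <- out[[h$qseqid]]
      if (is.null(cur) || better(h, cur)) out[[h$qseqid]] <- h
    }
    out
  }
  qt <- taxon_fun(hits$qseqid); st <- taxon_fun(hits$sseqid)
  fwd <- best_map(hits[qt == taxon_x & st == taxon_y, , drop = FALSE])
  rev <- best_map(hits[qt == taxon_y & st == taxon_x, , drop = FALSE])
  res <- list()
  for (q in names(fwd)) {
    s <- fwd[[q]]$sseqid
    if (!is.null(rev[[s]]) && rev[[s]]$sseqid == q)
      res[[q]] <- data.frame(a = q, b = s, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(a = character(0), b = character(0))
  out[order(out$a), , drop = FALSE]
}

# independently coded truth-table matcher over symbol strings
oracle_phenotype_rows <- list(
  parental_de  = "D.....",
  novel_sun    = ".D.D.D",
  novel_lem    = "..D.DD",
  novel_both   = ".DDDDE",
  sun_bro_like = "DE.D..",
  sun_fru_like = "DD.E..",
  lem_bro_like = "D.E.D.",
  lem_fru_like = "D.D.E.",
  both_bro_like = "DEEDDE",
  both_fru_like = "DDDEEE",
  hybrid_de    = ".....D")

oracle_classify <- function(flags) {
  hit <- vapply(oracle_phenotype_rows, function(row) {
    cells <- strsplit(row, "")[[1]]
    for (j in 1:6) {
      if (cells[j] == "D" && !flags[j]) return(FALSE)
      if (cells[j] == "E" && flags[j]) return(FALSE)
    }
    TRUE
  }, logical(1))
  names(oracle_phenotype_rows)[hit]
}

# random hit table for round-trip / RBBH oracle checks
random_hit_table <- function(n, n_x = 8, n_y = 8, seed = 1) {
  set.seed(seed)
  qx <- paste0("X|t", seq_len(n_x))
  qy <- paste0("Y|t", seq_len(n_y))
  q <- character(n); s <- character(n)
  fwd <- runif(n) < 0.5
  q[fwd] <- sample(qx, sum(fwd), replace = TRUE)
  s[fwd] <- sample(qy, sum(fwd), replace = TRUE)
  q[!fwd] <- sample(qy, sum(!fwd), replace = TRUE)
  s[!fwd] <- sample(qx, sum(!fwd), replace = TRUE)
  len <- sample(100:900, n, replace = TRUE)
  h <- data.frame(qseqid = q, sseqid = s,
                  pident = round(runif(n, 70, 100), 2),
                  length = len, mismatch = sample(0:50, n, replace = TRUE),
                  gapopen = sample(0:5, n, replace = TRUE),
                  qstart = 1L, qend = len, sstart = 1L, send = len,
                  evalue = signif(10^-runif(n, 0, 50), 4),
                  bitscore = sample(seq(50, 500, by = 0.5), n, replace = TRUE),
                  stringsAsFactors = FALSE)
  class(h) <- c("hit_table", "data.frame")
  h
}

# hand-built RBBH class table with prescribed direction structure
make_classes <- function(n_reciprocal, n_same, same_sign = -1) {
  n <- n_reciprocal + n_same
  if (!n) stop("empty class table")
  la <- c(rep(-1, n_reciprocal), rep(same_sign, n_same))
  lb <- c(rep(1, n_reciprocal), rep(same_sign, n_same))
  data.frame(a = paste0("X|p", seq_len(n)), b = paste0("Y|p", seq_len(n)),
             de_a = TRUE, de_b = TRUE, logFC_a = la, logFC_b = lb,
             category = "both",
             relation = c(rep("reciprocal", n_reciprocal),
                          rep("same_direction", n_same)),
             stringsAsFactors = FALSE)
}
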