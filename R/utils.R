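`%||%` <- function(a, b) if (is.null(a)) b else a

# geometric mean of a positive vector
geomean <- function(x) exp(mean(log(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

check_count_matrix <- function(counts) {
  if (!is_count_matrix(counts))
    stopf("'counts' must be a numeric matrix with locus rownames and sample colnames")
  if (any(counts < 0)) stopf("'counts' contains negative values")
  if (any(counts != round(counts))) stopf("'counts' must be integral")
  invisible(counts)
}

check_samples <- function(samples, counts = NULL) {
  need <- c("sample", "taxon", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stopf("sample sheet must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stopf("duplicate sample ids in sample sheet")
  if (!is.null(counts) && !setequal(colnames(counts), samples$sample))
    stopf("sample sheet does not match the columns of the count matrix")
  invisible(samples)
}
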