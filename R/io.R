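#' Read / write a count matrix as TSV
#'
#' Layout: first column the locus id, remaining columns one per sample.
#'
#' @param path file path.
#' @return integer matrix with locus rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("count matrix '%s' has no sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stopf("count matrix '%s' contains non-count values", path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_matrix
#' @param counts integer matrix.
#' @param id_col name for the locus id column.
#' @export
write_count_matrix <- function(counts, path, id_col = "locus") {
  df <- data.frame(counts[, 0, drop = FALSE], check.names = FALSE)
  df[[id_col]] <- rownames(counts)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (sample, taxon, replicate) as TSV
#'
#' @param path file path.
#' @return data.frame with columns sample, taxon, replicate.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "taxon", "replicate")
  if (!all(need %in% names(df)))
    stopf("sample sheet '%s' lacks column(s): %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  check_samples(df)
  df
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param path output file.
#' @param headers optional header strings (default the sequence names).
#' @export
write_fasta <- function(sequences, path, headers = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (!is.null(headers)) names(sequences) <- headers
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write simulated orthogroup sequences with structured headers
#'
#' Headers follow `<og>|<genus>|<taxon>|<transcript>`.
#'
#' @param og_sim output of [simulate_orthogroup_sequences()].
#' @param path output FASTA file.
#' @export
write_og_fasta <- function(og_sim, path) {
  m <- og_sim$ogs$members
  headers <- paste(m$og, m$genus, m$taxon, m$transcript, sep = "|")
  write_fasta(og_sim$sequences[m$transcript], path, headers)
}
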