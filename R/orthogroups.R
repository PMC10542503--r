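new_orthogroup_set <- function(ids, members) {
  stopifnot(all(c("og", "transcript", "taxon", "genus") %in% names(members)))
  structure(list(ids = ids, members = members), class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat(sprintf("orthogroup set: %d orthogroups, %d members, %d taxa\n",
              length(x$ids), nrow(x$members),
              length(unique(x$members$taxon))))
  invisible(x)
}

#' Parse orthogroup membership (Orthogroups.tsv dialect)
#'
#' Expects a header row naming the species columns, then one row per
#' orthogroup: the orthogroup id followed by comma-separated gene lists per
#' species (possibly empty). Fully empty rows are skipped with a warning.
#'
#' @param path file path.
#' @param taxon_map optional named vector taxon -> genus; taxa absent from
#'   the map keep their taxon label as genus.
#' @return an `orthogroup_set`: list with `ids` (all orthogroup ids, in file
#'   order) and `members` (data.frame og / transcript / taxon / genus).
#' @export
parse_orthogroups <- function(path, taxon_map = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stopf("empty orthogroup file: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  taxa <- header[-1]
  body <- lines[-1]
  blank <- !nzchar(trimws(gsub("\t", "", body)))
  if (any(blank)) {
    warnf("skipping %d empty orthogroup row(s)", sum(blank))
    body <- body[!blank]
  }
  if (!length(body))
    return(new_orthogroup_set(character(0),
                              data.frame(og = character(0),
                                         transcript = character(0),
                                         taxon = character(0),
                                         genus = character(0),
                                         stringsAsFactors = FALSE)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc > length(header)))
    stopf("orthogroup row %d has %d fields, header has %d",
          which(nc > length(header))[1] + 1L, max(nc), length(header))
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("duplicate orthogroup id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(seq_along(parts), function(i) {
    cells <- c(parts[[i]][-1], rep("", length(taxa) - (nc[i] - 1L)))
    genes <- lapply(cells, function(cell) {
      g <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      g[nzchar(g)]
    })
    n <- lengths(genes)
    if (!sum(n)) return(NULL)
    data.frame(og = ids[i], transcript = unlist(genes),
               taxon = rep(taxa, n), stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, rows)
  if (is.null(members))
    members <- data.frame(og = character(0), transcript = character(0),
                          taxon = character(0), stringsAsFactors = FALSE)
  dup <- members[duplicated(members[c("og", "transcript")]), ]
  if (nrow(dup))
    stopf("duplicate member '%s' in orthogroup %s",
          dup$transcript[1], dup$og[1])
  members$genus <- if (is.null(taxon_map)) members$taxon else {
    g <- unname(taxon_map[members$taxon])
    ifelse(is.na(g), members$taxon, g)
  }
  rownames(members) <- NULL
  new_orthogroup_set(ids, members)
}

#' Write an orthogroup set in Orthogroups.tsv layout
#'
#' @param ogs an `orthogroup_set`.
#' @param path output file.
#' @param taxa optional species column order; default all taxa present.
#' @export
write_orthogroups <- function(ogs, path, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(ogs$members$taxon))
  lines <- c(paste(c("Orthogroup", taxa), collapse = "\t"))
  for (id in ogs$ids) {
    m <- ogs$members[ogs$members$og == id, , drop = FALSE]
    cells <- vapply(taxa, function(tx)
      paste(m$transcript[m$taxon == tx], collapse = ", "), "")
    lines <- c(lines, paste(c(id, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

subset_orthogroups <- function(ogs, keep_ids) {
  new_orthogroup_set(ogs$ids[ogs$ids %in% keep_ids],
                     ogs$members[ogs$members$og %in% keep_ids, , drop = FALSE])
}

#' Extract one-to-one orthogroups
#'
#' Keeps orthogroups with exactly one member in each required taxon and no
#' members in any other taxon.
#'
#' @param ogs an `orthogroup_set`.
#' @param required_taxa character vector of taxa.
#' @return the filtered `orthogroup_set`.
#' @export
one_to_one_orthogroups <- function(ogs, required_taxa) {
  if (!length(required_taxa)) stopf("'required_taxa' must be non-empty")
  keep <- vapply(ogs$ids, function(id) {
    tx <- ogs$members$taxon[ogs$members$og == id]
    setequal(tx, required_taxa) && !anyDuplicated(tx)
  }, logical(1))
  subset_orthogroups(ogs, ogs$ids[keep])
}

#' Orthogroup size summary
#'
#' Fraction of orthogroups with at most each threshold number of members.
#'
#' @param ogs an `orthogroup_set`.
#' @param thresholds integer thresholds.
#' @return named numeric vector of fractions.
#' @export
size_summary <- function(ogs, thresholds = c(5, 10)) {
  sizes <- table(factor(ogs$members$og, levels = ogs$ids))
  out <- vapply(thresholds, function(th) mean(sizes <= th), numeric(1))
  names(out) <- paste0("le_", thresholds)
  out
}

#' Filter accounting for the paralog-removal stage
#'
#' @param n_input,n_removed,n_untested counts of orthogroups entering the
#'   filter, removed as paralog-containing, and too small / single-genus to
#'   test.
#' @return list with the three inputs plus `n_kept` (tested and retained)
#'   and `n_retained` (everything not removed, i.e. kept plus untested).
#' @export
filter_report <- function(n_input, n_removed, n_untested = 0) {
  if (n_removed + n_untested > n_input)
    stopf("removed + untested exceeds input")
  list(n_input = n_input, n_removed = n_removed, n_untested = n_untested,
       n_kept = n_input - n_removed - n_untested,
       n_retained = n_input - n_removed)
}

#' Remove paralog-contaminated orthogroups by genus non-monophyly
#'
#' For every orthogroup with at least `min_size` members from at least two
#' genera, builds an alignment-free k-mer neighbor-joining gene tree, roots
#' it on a non-focal-genus leaf when one exists (midpoint otherwise), and
#' tests every genus with >= 2 members for monophyly. Orthogroups in which
#' any tested genus is non-monophyletic are removed as likely
#' paralog-containing; orthogroups too small or with a single genus are kept
#' untested (flagged).
#'
#' @param ogs an `orthogroup_set`.
#' @param sequences named character vector (or `DNAStringSet`) of member
#'   sequences keyed by transcript id.
#' @param focal_genus genus whose monophyly is of primary interest; other
#'   genera are preferred as outgroups for rooting.
#' @param k k-mer length for the distance backend.
#' @param min_size minimum orthogroup size to test.
#' @return list with `kept`, `removed`, `untested` (orthogroup id vectors;
#'   a partition of the input), per-orthogroup `calls` and a
#'   [filter_report()].
#' @export
filter_paralogous_orthogroups <- function(ogs, sequences, focal_genus,
                                          k = 6, min_size = 4) {
  ids <- ogs$ids
  status <- character(length(ids))
  for (i in seq_along(ids)) {
    m <- ogs$members[ogs$members$og == ids[i], , drop = FALSE]
    if (nrow(m) < min_size || length(unique(m$genus)) < 2) {
      status[i] <- "untested"
      next
    }
    missing <- setdiff(m$transcript, names(sequences))
    if (length(missing))
      stopf("no sequence for member(s) of %s: %s", ids[i],
            paste(utils::head(missing, 3), collapse = ", "))
    D <- kmer_distance_matrix(sequences[m$transcript], k = k)
    tree <- neighbor_joining(D)
    genus_of <- stats::setNames(m$genus, m$transcript)
    mono <- genus_monophyly(tree, genus_of,
                            outgroup_genera = setdiff(unique(m$genus),
                                                      focal_genus))
    tested <- names(mono)[table(m$genus)[names(mono)] >= 2]
    status[i] <- if (length(tested) && !all(mono[tested])) "removed" else "kept"
  }
  calls <- data.frame(og = ids, status = status, stringsAsFactors = FALSE)
  list(kept = ids[status == "kept"],
       removed = ids[status == "removed"],
       untested = ids[status == "untested"],
       calls = calls,
       report = filter_report(length(ids), sum(status == "removed"),
                              sum(status == "untested")))
}
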