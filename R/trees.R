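#' Alignment-free k-mer cosine distance matrix
#'
#' Distance between two sequences is 1 minus the cosine similarity of their
#' k-mer count vectors. Zero diagonal, symmetric, values in \[0, 1\].
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`;
#'   every sequence must be at least `k` long.
#' @param k k-mer length.
#' @return symmetric numeric matrix with sequence names as dimnames.
#' @export
kmer_distance_matrix <- function(sequences, k = 6) {
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (length(sequences) < 2) stopf("need at least two sequences")
  w <- Biostrings::width(sequences)
  if (any(w < k))
    stopf("sequence(s) shorter than k = %d: %s", k,
          paste(utils::head(names(sequences)[w < k], 3), collapse = ", "))
  km <- Biostrings::oligonucleotideFrequency(sequences, width = k)
  norm <- sqrt(rowSums(km^2))
  unit <- km / norm
  D <- 1 - tcrossprod(unit)
  D[D < 0] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(names(sequences), names(sequences))
  D
}

#' Neighbor-joining gene tree
#'
#' Standard NJ agglomeration (via [ape::nj()]) with negative branch lengths
#' clamped to zero.
#'
#' @param distances square symmetric distance matrix, n >= 3, with leaf
#'   names as dimnames.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stopf("'distances' must be a square matrix")
  if (max(abs(distances - t(distances))) > 1e-8)
    stopf("'distances' must be symmetric")
  if (nrow(distances) < 3) stopf("need at least three leaves")
  tree <- ape::nj(distances)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Test genera for monophyly on a gene tree
#'
#' For each tested genus the tree is rooted on a leaf outside that genus —
#' preferring an outgroup-genus leaf, lexicographically first for
#' determinism — and the genus is monophyletic iff its leaves form a
#' complete clade of the rooted tree. Because any root outside the genus
#' gives the same answer, this is equivalent to asking whether the genus's
#' leaves form one side of a split of the unrooted tree. Genera with a
#' single leaf, or spanning every leaf, are vacuously monophyletic.
#'
#' @param tree a `phylo` tree.
#' @param genus_of named character vector leaf label -> genus, covering all
#'   leaves.
#' @param outgroup_genera genera preferred for rooting.
#' @param genera genera to test; default all genera on the tree.
#' @return named logical vector, one entry per tested genus.
#' @export
genus_monophyly <- function(tree, genus_of, outgroup_genera = NULL,
                            genera = NULL) {
  tips <- tree$tip.label
  if (!all(tips %in% names(genus_of)))
    stopf("genus missing for leaf(s): %s",
          paste(utils::head(setdiff(tips, names(genus_of)), 3),
                collapse = ", "))
  gv <- genus_of[tips]
  if (is.null(genera)) genera <- sort(unique(gv))
  absent <- setdiff(genera, gv)
  if (length(absent))
    stopf("genus not on the tree: %s", paste(absent, collapse = ", "))
  out <- vapply(genera, function(g) {
    leaves <- tips[gv == g]
    if (length(leaves) <= 1 || length(leaves) == length(tips)) return(TRUE)
    og_tips <- sort(tips[gv %in% outgroup_genera & gv != g])
    root_tip <- if (length(og_tips)) og_tips[1] else sort(tips[gv != g])[1]
    rooted <- ape::root(tree, outgroup = root_tip, resolve.root = TRUE)
    ape::is.monophyletic(rooted, leaves)
  }, logical(1))
  names(out) <- genera
  out
}
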