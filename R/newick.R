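#' Write a phylogram to a Newick file
#'
#' Branch lengths are always emitted; internal node labels (e.g. bootstrap
#' supports attached by [bootstrap_support()]) are preserved. Reading the file
#' back with [read_newick()] reproduces the topology, branch lengths (to
#' 1e-9) and supports.
#'
#' @param tree an [ape::phylo] object with labelled tips.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("every leaf must be labelled")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path file path.
#' @return an [ape::phylo] object; internal labels are kept as `node.label`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Unrooted bipartitions of a tree
#'
#' Each internal edge splits the leaf set in two; a bipartition is represented
#' canonically as the sorted label set of the side NOT containing the
#' alphabetically first leaf, so representations are comparable across
#' differently rooted copies of the same unrooted topology. Trivial splits
#' (single leaf) are omitted.
#'
#' @param tree an [ape::phylo] object.
#' @return character vector of canonical splits, one string per internal edge.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    labs <- tree$tip.label[p]
    if (length(labs) <= 1L || length(labs) >= n - 1L) next
    if (anchor %in% labs) labs <- setdiff(tree$tip.label, labs)
    out <- c(out, paste(sort(labs), collapse = "|"))
  }
  unique(out)
}
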