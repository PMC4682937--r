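# Independent oracles used across test files.

# closed-form upper tail of the 1-df chi-square via the complementary
# error function (independent of pchisq)
erfc_tail_p <- function(stat) pracma::erfc(sqrt(stat / 2))

# brute-force longest strictly increasing subsequence length by
# enumerating every subsequence (bitmask); feasible for n <= 12
brute_lis_len <- function(v) {
  n <- length(v)
  best <- 0L
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    if (all(diff(v[idx]) > 0)) best <- length(idx)
  }
  best
}

# random unrooted binary tree with positive branch lengths and its exact
# additive (path-length) distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# four-point condition oracle for the 4-taxon unrooted topology: the pair
# grouping with the smallest pairwise sum is the split
four_point_split <- function(D) {
  labs <- rownames(D)
  s12 <- D[1, 2] + D[3, 4]
  s13 <- D[1, 3] + D[2, 4]
  s14 <- D[1, 4] + D[2, 3]
  pick <- which.min(c(s12, s13, s14))
  sides <- list(c(1, 2), c(1, 3), c(1, 4))[[pick]]
  paste(sort(labs[sides]), collapse = "|")
}
canonical_quartet_split <- function(tree) {
  # express a 4-taxon tree's single internal split as the side holding the
  # alphabetically first label
  bp <- bipartitions(tree)
  anchor <- sort(tree$tip.label)[1L]
  side <- strsplit(bp, "|", fixed = TRUE)[[1L]]
  if (!(anchor %in% side)) side <- setdiff(tree$tip.label, side)
  paste(sort(side), collapse = "|")
}

# minimal Procrustes residual of Y onto X (centering + optimal rotation,
# no scaling needed when configurations are congruent)
procrustes_error <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sqrt(sum((Y %*% R - X)^2))
}

# path-length (cophenetic) distances of a phylo, rows/cols sorted by label
tree_distances <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D))]
}

# a small nested ("perfectly congruent") marker panel on 6 accessions:
# every marker supports the same hierarchy ((A,B),C),((D,E),F)
congruent_panel <- function(copies = 30L) {
  pats <- list(c(1, 1, 1, 1, 1, 1),
               c(1, 1, 0, 0, 0, 0),
               c(1, 1, 1, 0, 0, 0),
               c(0, 0, 0, 1, 1, 0),
               c(0, 0, 0, 1, 1, 1))
  m <- do.call(cbind, rep(pats, each = copies))
  rownames(m) <- LETTERS[1:6]
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  marker_matrix(m)
}
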