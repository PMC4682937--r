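#' Neighbour-joining phylogram from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion. On an exactly additive
#' distance matrix the generating topology and branch lengths are recovered
#' (to 1e-9). Ties in the Q-criterion are broken deterministically by the
#' smallest label pair (each cluster represented by its alphabetically first
#' leaf). Negative branch-length estimates are clamped to zero in the output;
#' the raw estimates are kept in `attr(tree, "raw_edge_lengths")`.
#'
#' @param D symmetric distance matrix with labelled rows (or a
#'   [nei_li_distance()] result, whose `D` component is used).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "neili_dist")) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least three labels")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (any(!is.finite(D)))
    stop("distance matrix has saturated/undefined entries; ",
         "cap them or remove the affected pairs before tree building")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")

  # each active cluster: newick fragment, representative (smallest) leaf label
  frag <- labs
  rep_lab <- labs
  d <- D
  while (nrow(d) > 3L) {
    m <- nrow(d)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    key2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # resolve the final three clusters around one internal node
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  tree <- ape::read.tree(text = nwk)
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge_lengths") <- raw
  tree
}

#' Bootstrap clade support for the neighbour-joining phylogram
#'
#' Resamples marker columns with replacement `B` times; each replicate
#' rebuilds the Nei-Li distance matrix and the NJ tree. The support of each
#' internal edge of the original tree is the percentage of replicates whose
#' tree contains the same (unrooted) bipartition. Replicates whose distance
#' matrix is degenerate (saturated/undefined pairs) are dropped and the
#' effective replicate count reported.
#'
#' @param x a [marker_matrix()] (>= 4 accessions).
#' @param B bootstrap replicates (default 1000); `B = 0` returns the original
#'   tree without supports.
#' @param seed RNG seed (resampling is deterministic given the seed).
#' @param r restriction-site length for [nei_li_distance()].
#' @param cap saturation cap passed to [nei_li_distance()].
#' @return the original NJ tree with supports as `node.label` (empty at the
#'   root/trivial splits) and attributes `effective_B` and `dropped`.
#' @export
bootstrap_support <- function(x, B = 1000L, seed = 1L, r = 6, cap = NA_real_) {
  if (nrow(x) < 4L) stop("need at least four accessions for supports")
  orig <- neighbor_joining(nei_li_distance(x, r = r, cap = cap))
  if (B == 0L) return(orig)
  set.seed(seed)
  # canonical split per internal node of the original tree
  node_split <- node_bipartitions(orig)
  tally <- stats::setNames(numeric(length(node_split)), names(node_split))
  eff <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
    xb <- marker_matrix(unclass(x)[, cols, drop = FALSE],
                        marker_ids = sprintf("bs%05d", seq_len(ncol(x))))
    db <- nei_li_distance(xb, r = r, cap = cap)
    if (any(!is.finite(db$D))) next
    bp <- bipartitions(neighbor_joining(db))
    eff <- eff + 1L
    hit <- node_split[!is.na(node_split) & node_split %in% bp]
    tally[names(hit)] <- tally[names(hit)] + 1
  }
  if (eff == 0L) stop("all bootstrap replicates degenerate")
  lab <- rep("", orig$Nnode)
  internal <- !is.na(node_split)
  lab[internal] <- as.character(round(100 * tally[internal] / eff))
  orig$node.label <- lab
  attr(orig, "effective_B") <- eff
  attr(orig, "dropped") <- B - eff
  orig
}

# canonical bipartition string for every internal node (NA for trivial splits)
node_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  parts <- ape::prop.part(tree)
  out <- rep(NA_character_, tree$Nnode)
  for (k in seq_along(parts)) {
    labs <- tree$tip.label[parts[[k]]]
    if (length(labs) <= 1L || length(labs) >= n - 1L) next
    if (anchor %in% labs) labs <- setdiff(tree$tip.label, labs)
    out[k] <- paste(sort(labs), collapse = "|")
  }
  names(out) <- paste0("nd", seq_len(tree$Nnode))
  out
}

#' Root a phylogram at an outgroup accession
#'
#' Outgroup rooting on a named leaf; if the leaf is absent, midpoint-style
#' rooting at the longest-path centre is used as fallback.
#'
#' @param tree an [ape::phylo].
#' @param outgroup leaf label to root with.
#' @return a rooted [ape::phylo].
#' @export
root_phylogram <- function(tree, outgroup) {
  if (outgroup %in% tree$tip.label)
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  else {
    warning("outgroup '", outgroup, "' not in tree; using midpoint-style root")
    ape::root(tree, outgroup = tree$tip.label[which.max(
      ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])],
      resolve.root = TRUE)
  }
}
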