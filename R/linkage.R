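#' Haldane map function and its inverse
#'
#' Converts a recombination fraction to map distance assuming no crossover
#' interference: cM = -50 ln(1 - 2 rf); `haldane_inv()` is exact.
#'
#' @param rf recombination fraction in \[0, 0.5).
#' @param cm map distance in centimorgans (>= 0).
#' @return map distance in cM, or recombination fraction.
#' @export
haldane <- function(rf) {
  if (any(rf < 0 | rf >= 0.5)) stop("rf must lie in [0, 0.5)")
  -50 * log(1 - 2 * rf)
}

#' @rdname haldane
#' @export
haldane_inv <- function(cm) {
  if (any(cm < 0)) stop("cm must be >= 0")
  0.5 * (1 - exp(-cm / 50))
}

#' Two-point linkage between testcross markers of one parent
#'
#' For two 1:1 testcross markers segregating from the same parent, the
#' recombination fraction is estimated from the mismatch count d over the n
#' jointly scored progeny: rf = min(d, n-d)/n, phase coupling when d <= n-d
#' (else repulsion), and LOD = k log10(2 rf) + (n-k) log10(2(1-rf)) with k
#' the recombinant count under the chosen phase (0 log 0 = 0).
#'
#' @param m1,m2 progeny call vectors (0/1/NA) of the two markers.
#' @param min_overlap minimum jointly scored progeny (default 20).
#' @return list with `rf`, `phase`, `lod`, `n_informative`, `computed`.
#' @export
two_point <- function(m1, m2, min_overlap = 20L) {
  ok <- !is.na(m1) & !is.na(m2)
  n <- sum(ok)
  if (n < min_overlap)
    return(list(rf = NA_real_, phase = NA_character_, lod = NA_real_,
                n_informative = n, computed = FALSE))
  d <- sum(m1[ok] != m2[ok])
  k <- min(d, n - d)
  rf <- k / n
  phase <- if (d <= n - d) "coupling" else "repulsion"
  lg <- function(v) ifelse(v > 0, log10(v), 0)  # 0*log10(0) convention
  lod <- k * lg(2 * rf) + (n - k) * lg(2 * (1 - rf))
  list(rf = rf, phase = phase, lod = lod, n_informative = n, computed = TRUE)
}

#' Independence LOD between two markers
#'
#' G-squared statistic of independence on the 2x2 progeny presence table,
#' expressed on the LOD scale as G^2 / (2 ln 10). Valid between any pair of
#' classified markers, including pairs from different parents. Zero cells
#' follow the 0 ln 0 = 0 convention.
#'
#' @param m1,m2 progeny call vectors (0/1/NA).
#' @param min_overlap minimum jointly scored progeny (default 20).
#' @return list with `lod`, `g2`, `n_informative`, `computed`; a marker
#'   constant in the overlap gives LOD 0 with a warning.
#' @export
independence_lod <- function(m1, m2, min_overlap = 20L) {
  ok <- !is.na(m1) & !is.na(m2)
  n <- sum(ok)
  if (n < min_overlap)
    return(list(lod = NA_real_, g2 = NA_real_, n_informative = n,
                computed = FALSE))
  a <- m1[ok]; b <- m2[ok]
  obs <- c(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
           sum(a == 0 & b == 1), sum(a == 0 & b == 0))
  ra <- c(sum(a == 1), sum(a == 0))
  rb <- c(sum(b == 1), sum(b == 0))
  if (any(ra == 0) || any(rb == 0)) {
    warning("marker constant among jointly scored progeny; LOD set to 0")
    return(list(lod = 0, g2 = 0, n_informative = n, computed = TRUE))
  }
  expd <- c(ra[1] * rb[1], ra[1] * rb[2], ra[2] * rb[1], ra[2] * rb[2]) / n
  terms <- ifelse(obs > 0, obs * log(obs / expd), 0)
  g2 <- 2 * sum(terms)
  list(lod = g2 / (2 * log(10)), g2 = g2, n_informative = n, computed = TRUE)
}

#' Pairwise independence LODs for a marker matrix
#'
#' @param x a [marker_matrix()] of progeny calls (accessions x markers).
#' @param min_overlap minimum jointly scored progeny per pair.
#' @return data frame: `marker1`, `marker2`, `lod`, `n_informative`.
#' @export
pairwise_lod <- function(x, min_overlap = 20L) {
  ids <- colnames(x)
  m <- length(ids)
  pairs <- utils::combn(m, 2L)
  res <- data.frame(marker1 = ids[pairs[1L, ]], marker2 = ids[pairs[2L, ]],
                    lod = NA_real_, n_informative = NA_integer_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    r <- suppressWarnings(
      independence_lod(x[, pairs[1L, p]], x[, pairs[2L, p]], min_overlap))
    res$lod[p] <- r$lod
    res$n_informative[p] <- r$n_informative
  }
  res
}

#' Group markers into linkage groups by LOD threshold
#'
#' Single-linkage transitive closure over marker pairs with LOD strictly
#' above the threshold; unlinked markers remain singletons. Groups are
#' numbered by decreasing size, ties by the lexicographically smallest
#' member, so numbering is deterministic.
#'
#' @param pairs data frame with `marker1`, `marker2`, `lod` (e.g. from
#'   [pairwise_lod()]); rows with `NA` LOD are ignored.
#' @param markers full marker ID set (so singletons are retained); defaults
#'   to the IDs present in `pairs`.
#' @param lod_threshold grouping threshold (default 5; linkage requires
#'   LOD > threshold).
#' @return data frame: `marker`, `group` (integer).
#' @export
group_markers <- function(pairs, markers = NULL, lod_threshold = 5) {
  if (is.null(markers))
    markers <- sort(unique(c(pairs$marker1, pairs$marker2)))
  idx <- stats::setNames(seq_along(markers), markers)
  parent <- seq_along(markers)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  linked <- pairs[!is.na(pairs$lod) & pairs$lod > lod_threshold, , drop = FALSE]
  for (p in seq_len(nrow(linked))) {
    ri <- find(idx[[linked$marker1[p]]])
    rj <- find(idx[[linked$marker2[p]]])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_along(markers), find, 0L)
  groups <- split(markers, comp)
  size <- lengths(groups)
  first <- vapply(groups, function(g) sort(g)[1L], "")
  ord <- order(-size, first)
  gnum <- integer(length(markers))
  for (g in seq_along(ord))
    gnum[markers %in% groups[[ord[g]]]] <- g
  data.frame(marker = markers, group = gnum, stringsAsFactors = FALSE)
}

#' Genetic-map summary statistics
#'
#' Per linkage group and overall: marker counts, map length (max - min
#' position), adjacent-marker spacing, and gaps wider than a threshold.
#' Two definitions of the average marker distance are reported: total length
#' over marker count, and the mean adjacent interval.
#'
#' @param map data frame with columns `marker`, `lg`, `cm`.
#' @param gap_threshold report gaps strictly wider than this (cM, default 8).
#' @return list with `per_lg` (data frame: lg, n_markers, length_cm, n_gaps,
#'   max_gap), `gaps` (data frame of all gaps above threshold), and `total`
#'   (total_length_cm, n_markers, n_lgs, mean_dist_length_over_markers,
#'   mean_adjacent_interval, largest_gap).
#' @export
map_stats <- function(map, gap_threshold = 8) {
  stopifnot(all(c("marker", "lg", "cm") %in% names(map)))
  per <- lapply(split(map, map$lg), function(m) {
    pos <- sort(m$cm)
    sp <- if (length(pos) > 1L) diff(pos) else numeric(0)
    gaps <- sp[sp > gap_threshold]
    list(lg = m$lg[1L], n_markers = nrow(m),
         length_cm = if (length(pos) > 1L) max(pos) - min(pos) else 0,
         spacings = sp, n_gaps = length(gaps),
         max_gap = if (length(sp)) max(sp) else NA_real_)
  })
  per_lg <- do.call(rbind, lapply(per, function(p)
    data.frame(lg = p$lg, n_markers = p$n_markers, length_cm = p$length_cm,
               n_gaps = p$n_gaps, max_gap = p$max_gap,
               stringsAsFactors = FALSE)))
  rownames(per_lg) <- NULL
  all_sp <- unlist(lapply(per, `[[`, "spacings"))
  gaps <- do.call(rbind, lapply(per, function(p) {
    g <- p$spacings[p$spacings > gap_threshold]
    if (!length(g)) return(NULL)
    data.frame(lg = p$lg, gap_cm = g, stringsAsFactors = FALSE)
  }))
  total_len <- sum(per_lg$length_cm)
  list(per_lg = per_lg,
       gaps = if (is.null(gaps)) data.frame(lg = character(0),
                                            gap_cm = numeric(0)) else gaps,
       total = list(total_length_cm = total_len,
                    n_markers = nrow(map), n_lgs = nrow(per_lg),
                    n_gaps = sum(per_lg$n_gaps),
                    largest_gap = if (length(all_sp)) max(all_sp) else NA_real_,
                    mean_dist_length_over_markers = total_len / nrow(map),
                    mean_adjacent_interval =
                      if (length(all_sp)) mean(all_sp) else NA_real_))
}
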