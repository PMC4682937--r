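#' Longest strictly increasing subsequence
#'
#' Dynamic-programming LIS returning the indices of one longest strictly
#' increasing subsequence, deterministically (the lexicographically smallest
#' index chain among those of maximal length).
#'
#' @param v numeric vector without `NA`.
#' @return integer indices of the subsequence (in order).
#' @export
lis <- function(v) {
  n <- length(v)
  if (!n) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    js <- which(v[seq_len(i - 1L)] < v[i])
    if (length(js)) {
      best <- max(len[js])
      len[i] <- best + 1L
      prev[i] <- js[len[js] == best][1L]
    }
  }
  L <- max(len)
  end <- which(len == L)[1L]
  out <- integer(L)
  for (k in L:1) { out[k] <- end; end <- prev[end] }
  out
}

#' Roman-prefix homoeology group of a linkage-group name
#'
#' Linkage groups are named by the Roman numeral of their homoeology group
#' plus a homoeologue index, e.g. `"II-2"`; the expected diploid reference
#' pseudochromosome is the Arabic value of the Roman prefix (I-VII -> 1-7).
#'
#' @param lg character vector of linkage-group names.
#' @return integer expected chromosome per LG.
#' @export
expected_chromosome <- function(lg) {
  prefix <- toupper(sub("[^IVXivx].*$", "", sub("-.*$", "", trimws(lg))))
  roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L, VI = 6L, VII = 7L)
  out <- roman[prefix]
  if (anyNA(out))
    stop("cannot parse Roman homoeology-group prefix from LG name(s): ",
         paste(unique(lg[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Chromosome concordance between genetic and physical positions
#'
#' A marker is discordant when its physical chromosome differs from the one
#' expected from its linkage group's homoeology group. Markers without a
#' physical anchor are excluded from the denominator and counted separately.
#'
#' @param anchors data frame with columns `marker`, `lg`, `chr` (physical
#'   chromosome, `NA` when unanchored); further columns are passed through.
#' @param expected optional integer vector of expected chromosomes (defaults
#'   to [expected_chromosome()] on `lg`).
#' @return list with `per_marker` (anchors plus `expected_chr`,
#'   `concordant`), and `summary` (n_anchored, n_unanchored, n_discordant,
#'   pct_discordant rounded to one decimal).
#' @export
chromosome_concordance <- function(anchors, expected = NULL) {
  stopifnot(all(c("marker", "lg", "chr") %in% names(anchors)))
  if (is.null(expected)) expected <- expected_chromosome(anchors$lg)
  anchored <- !is.na(anchors$chr)
  conc <- ifelse(anchored, anchors$chr == expected, NA)
  per <- cbind(anchors, expected_chr = expected, concordant = conc)
  n_anch <- sum(anchored)
  n_disc <- sum(!conc, na.rm = TRUE)
  list(per_marker = per,
       summary = list(n_anchored = n_anch,
                      n_unanchored = sum(!anchored),
                      n_discordant = n_disc,
                      pct_discordant = round(100 * n_disc / n_anch, 1)))
}

#' Scale physical positions for co-plotting with a genetic map
#'
#' Physical coordinates in base pairs are converted to megabases and
#' multiplied by a scale factor (default 4) so that they span a range
#' comparable to an octoploid genetic map in centimorgans.
#'
#' @param bp physical positions in base pairs.
#' @param factor scale factor (default 4).
#' @return plot coordinates, `(bp / 1e6) * factor`.
#' @export
scale_physical <- function(bp, factor = 4) {
  (bp / 1e6) * factor
}

#' Detect marker-order rearrangements within a linkage group
#'
#' Orders anchored markers by genetic position (ties broken by physical
#' position, then marker ID) and computes the longest strictly increasing
#' and decreasing subsequences of their physical positions. The longer one
#' is the colinear backbone (orientation forward/reverse; ties favour
#' forward); markers off the backbone are rearrangement candidates. Maximal
#' runs of at least 3 consecutive candidates that are internally monotone
#' against the backbone orientation are flagged as inverted blocks. Kendall
#' tau between genetic and physical order is reported per linkage group.
#'
#' @param anchors data frame with columns `marker`, `lg`, `cm`, `chr`, `bp`.
#' @param min_markers skip LGs with fewer anchored markers (default 5).
#' @return list with `per_lg` (lg, n_anchored, orientation, backbone_size,
#'   n_candidates, kendall_tau), `candidates` (lg, marker, cm, bp),
#'   `blocks` (lg, block, marker, cm, bp) and `skipped` (LG names).
#' @export
detect_rearrangements <- function(anchors, min_markers = 5L) {
  stopifnot(all(c("marker", "lg", "cm", "chr", "bp") %in% names(anchors)))
  anchors <- anchors[!is.na(anchors$bp) & !is.na(anchors$cm), , drop = FALSE]
  per_lg <- NULL; cands <- NULL; blocks <- NULL; skipped <- character(0)
  for (g in unique(anchors$lg)) {
    a <- anchors[anchors$lg == g, , drop = FALSE]
    if (nrow(a) < min_markers) {
      skipped <- c(skipped, g)
      message("LG ", g, ": fewer than ", min_markers,
              " anchored markers; skipped")
      next
    }
    a <- a[order(a$cm, a$bp, a$marker), , drop = FALSE]
    v <- a$bp
    inc <- lis(v)
    dec <- lis(-v)
    forward <- length(inc) >= length(dec)
    backbone <- if (forward) inc else dec
    off <- setdiff(seq_along(v), backbone)
    tau <- suppressWarnings(stats::cor(a$cm, v, method = "kendall"))
    per_lg <- rbind(per_lg, data.frame(
      lg = g, n_anchored = nrow(a),
      orientation = if (forward) "forward" else "reverse",
      backbone_size = length(backbone), n_candidates = length(off),
      kendall_tau = tau, stringsAsFactors = FALSE))
    if (length(off))
      cands <- rbind(cands, data.frame(lg = g, marker = a$marker[off],
                                       cm = a$cm[off], bp = v[off],
                                       stringsAsFactors = FALSE))
    # maximal runs of >= 3 consecutive candidates, monotone against the
    # backbone orientation; each run is then extended over flanking markers
    # that continue the reverse-monotone trend (an inversion endpoint can
    # legitimately sit on the increasing backbone)
    if (length(off) >= 3L) {
      runs <- split(off, cumsum(c(1L, diff(off) != 1L)))
      bid <- 0L
      going_down <- if (forward) function(x, y) x > y else function(x, y) x < y
      for (rn in runs) {
        if (length(rn) < 3L) next
        d <- diff(v[rn])
        rev_monotone <- if (forward) all(d < 0) else all(d > 0)
        if (!rev_monotone) next
        s <- min(rn); e <- max(rn)
        while (s > 1L && going_down(v[s - 1L], v[s])) s <- s - 1L
        while (e < length(v) && going_down(v[e], v[e + 1L])) e <- e + 1L
        bid <- bid + 1L
        blocks <- rbind(blocks, data.frame(
          lg = g, block = bid, marker = a$marker[s:e],
          cm = a$cm[s:e], bp = v[s:e], stringsAsFactors = FALSE))
      }
    }
  }
  empty_c <- data.frame(lg = character(0), marker = character(0),
                        cm = numeric(0), bp = numeric(0),
                        stringsAsFactors = FALSE)
  empty_b <- data.frame(lg = character(0), block = integer(0),
                        marker = character(0), cm = numeric(0),
                        bp = numeric(0), stringsAsFactors = FALSE)
  list(per_lg = per_lg,
       candidates = if (is.null(cands)) empty_c else cands,
       blocks = if (is.null(blocks)) empty_b else blocks,
       skipped = skipped)
}
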