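#' Polymorphism information content of a dominant marker
#'
#' For a dominant (presence/absence) biallelic marker with band frequency
#' `f`, PIC = 1 - f^2 - (1-f)^2 = 2 f (1-f), maximal (0.5) at f = 0.5 and
#' symmetric in f and 1-f.
#'
#' @param f band (presence) frequency in \[0,1\]; vectorised.
#' @return PIC value(s) in \[0, 0.5\].
#' @export
pic_dominant <- function(f) {
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE))
  2 * f * (1 - f)
}

#' Per-marker PIC summary of a marker matrix
#'
#' Band frequencies are computed over non-missing calls; markers with no
#' scored call get `NA`. The summary reports the mean PIC and the share of
#' markers in the conventional informativeness bins.
#'
#' @param x a [marker_matrix()].
#' @return list with `per_marker` (data frame: marker, band_freq, pic),
#'   `mean_pic`, and `bins` (percent of markers with PIC < 0.10, 0.10-0.30,
#'   0.30-0.40, 0.40-0.50, rounded to one decimal).
#' @export
pic_summary <- function(x) {
  scored <- colSums(!is.na(x))
  f <- ifelse(scored > 0, colSums(x == 1L, na.rm = TRUE) / scored, NA_real_)
  pic <- pic_dominant(ifelse(is.na(f), NA_real_, f))
  ok <- !is.na(pic)
  bins <- c(lt_0.10 = mean(pic[ok] < 0.10),
            r_0.10_0.30 = mean(pic[ok] >= 0.10 & pic[ok] < 0.30),
            r_0.30_0.40 = mean(pic[ok] >= 0.30 & pic[ok] < 0.40),
            r_0.40_0.50 = mean(pic[ok] >= 0.40))
  list(per_marker = data.frame(marker = colnames(x), band_freq = f, pic = pic,
                               stringsAsFactors = FALSE),
       mean_pic = mean(pic, na.rm = TRUE),
       bins = round(100 * bins, 1))
}

#' Genotyping quality metrics: call rate and scoring reproducibility
#'
#' Call rate is the non-missing fraction per marker. Reproducibility is
#' assessed from technical replicate pairs of accessions: per marker, the
#' fraction of replicate pairs whose two calls agree, among pairs where both
#' calls are scored.
#'
#' @param x a [marker_matrix()].
#' @param replicate_pairs two-column character matrix (or data frame) of
#'   accession ID pairs genotyped in technical replication; `NULL` if none.
#' @return list with `call_rate` (named per-marker), `mean_call_rate`,
#'   `reproducibility` (named per-marker, `NA` where no pair is scored; `NULL`
#'   when no pairs given) and `mean_reproducibility` (`NA` when no pairs).
#' @export
quality_metrics <- function(x, replicate_pairs = NULL) {
  call_rate <- colMeans(!is.na(x))
  rep_per_marker <- NULL
  mean_rep <- NA_real_
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0) {
    rp <- as.matrix(replicate_pairs)
    if (!all(rp %in% rownames(x)))
      stop("replicate pair refers to unknown accession(s): ",
           paste(setdiff(rp, rownames(x)), collapse = ", "))
    a <- x[rp[, 1L], , drop = FALSE]
    b <- x[rp[, 2L], , drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    agree <- colSums(a == b & both, na.rm = TRUE)
    denom <- colSums(both)
    rep_per_marker <- ifelse(denom > 0, agree / denom, NA_real_)
    names(rep_per_marker) <- colnames(x)
    mean_rep <- sum(agree) / sum(denom)
  }
  list(call_rate = call_rate, mean_call_rate = mean(call_rate),
       reproducibility = rep_per_marker, mean_reproducibility = mean_rep)
}

#' Solve fragment retention G from the shared-band fraction F
#'
#' Under the restriction-fragment divergence model the expected shared-band
#' fraction satisfies F = G^4 / (3 - 2G), with G the per-site fragment
#' retention probability. Solved by damped fixed-point iteration
#' G <- (F (3 - 2G))^(1/4) from G0 = F^(1/4).
#'
#' @param f shared-band fraction in (0, 1\].
#' @param tol convergence tolerance on |delta G| (default 1e-12).
#' @param max_iter iteration cap.
#' @return retention probability G in (0, 1\].
#' @export
solve_retention <- function(f, tol = 1e-12, max_iter = 10000L) {
  stopifnot(f > 0, f <= 1)
  g <- f^0.25
  for (i in seq_len(max_iter)) {
    g_new <- (f * (3 - 2 * g))^0.25
    g_new <- (g + g_new) / 2  # damping
    if (abs(g_new - g) < tol) return(g_new)
    g <- g_new
  }
  stop("retention solve did not converge for F = ", f)
}

#' Nei-Li restriction-fragment distance matrix
#'
#' For every accession pair, over markers scored in both: band counts n_x,
#' n_y and shared bands n_xy give F = 2 n_xy / (n_x + n_y); the retention G
#' is solved from F = G^4/(3 - 2G) (see [solve_retention()]); the distance is
#' D = -(2/r) ln G with r the restriction-site length. Identical profiles
#' give D = 0; pairs with no shared bands (F = 0) are saturated and set to
#' `cap`; pairs with no bands at all are undefined (`NA`).
#'
#' @param x a [marker_matrix()] (pairwise-complete over missing calls).
#' @param r restriction recognition-site length (default 6, PstI).
#' @param cap distance assigned to saturated pairs (default `NA`; supply a
#'   finite cap to make downstream tree building possible).
#' @return list of class `"neili_dist"`: `D` (symmetric distance matrix,
#'   zero diagonal), `F` (shared-band fractions), `G` (retentions),
#'   `saturated` and `undefined` (logical matrices).
#' @export
nei_li_distance <- function(x, r = 6, cap = NA_real_) {
  if (nrow(x) < 2L) stop("need at least two accessions")
  X1 <- (x == 1L & !is.na(x)) * 1
  S <- (!is.na(x)) * 1
  nxy <- tcrossprod(X1)                    # shared bands on complete markers
  nx_pair <- tcrossprod(X1, S)             # bands of i over markers scored in j
  tot <- nx_pair + t(nx_pair)
  Fm <- ifelse(tot > 0, 2 * nxy / tot, NA_real_)
  n <- nrow(x)
  G <- matrix(NA_real_, n, n, dimnames = dimnames(Fm))
  D <- matrix(NA_real_, n, n, dimnames = dimnames(Fm))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(Fm))
  und <- matrix(FALSE, n, n, dimnames = dimnames(Fm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { D[i, j] <- 0; G[i, j] <- 1; next }
    if (j < i)  { D[i, j] <- D[j, i]; G[i, j] <- G[j, i]
                  sat[i, j] <- sat[j, i]; und[i, j] <- und[j, i]; next }
    fij <- Fm[i, j]
    if (is.na(fij)) { und[i, j] <- TRUE; next }
    if (fij <= 0) { sat[i, j] <- TRUE; D[i, j] <- cap; next }
    G[i, j] <- solve_retention(fij)
    D[i, j] <- -(2 / r) * log(G[i, j])
  }
  structure(list(D = D, F = Fm, G = G, saturated = sat | t(sat),
                 undefined = und | t(und), r = r),
            class = "neili_dist")
}

#' @export
print.neili_dist <- function(x, ...) {
  cat(sprintf("neili_dist: %d accessions, r = %s, %d saturated pair(s)\n",
              nrow(x$D), format(x$r), sum(x$saturated) / 2))
  invisible(x)
}
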