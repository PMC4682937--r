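#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of -0.5 D^2 followed by
#' eigendecomposition (via [stats::cmdscale()]). Axes are ordered by
#' eigenvalue; the percent variance of axis i is lambda_i over the sum of
#' positive eigenvalues. Negative eigenvalues (non-Euclidean distances) are
#' reported but excluded from the denominator and carry no coordinates.
#'
#' @param D symmetric distance matrix, zero diagonal (or a
#'   [nei_li_distance()] result).
#' @return list with `coordinates` (accessions x axes), `eigenvalues`,
#'   and `percent_variance` (one value per returned axis).
#' @export
pcoa <- function(D) {
  if (inherits(D, "neili_dist")) D <- D$D
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  coords <- fit$points[, seq_len(min(pos, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pct <- 100 * eig[seq_len(ncol(coords))] / sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       percent_variance = pct)
}

#' Evanno delta-K statistic for subpopulation-number selection
#'
#' Given replicate log-probabilities L(K) from a model-based clustering
#' program over a consecutive range of K, computes for each interior K
#' \deqn{\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / sd(L(K))}
#' (sample standard deviation). The K with the largest delta-K marks the
#' strongest structural level. Endpoints are undefined.
#'
#' @param runs data frame with columns `k` and `loglik` (one row per
#'   replicate run), e.g. from [simulate_loglik_curves()].
#' @return list with `table` (data frame: k, n_runs, mean_loglik, sd_loglik,
#'   delta_k) and `best_k` (argmax of delta-K over interior K).
#' @export
delta_k <- function(runs) {
  stopifnot(is.data.frame(runs), all(c("k", "loglik") %in% names(runs)))
  ks <- sort(unique(runs$k))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1)) stop("K range must be consecutive")
  n_runs <- tapply(runs$loglik, factor(runs$k, levels = ks), length)
  if (any(n_runs < 2L)) stop("need >= 2 replicates for every K")
  m <- tapply(runs$loglik, factor(runs$k, levels = ks), mean)
  s <- tapply(runs$loglik, factor(runs$k, levels = ks), stats::sd)
  dk <- rep(NA_real_, length(ks))
  interior <- 2:(length(ks) - 1L)
  if (any(s[interior] == 0))
    stop("sd(L(K)) = 0 at interior K = ",
         paste(ks[interior][s[interior] == 0], collapse = ","),
         "; delta-K divisor degenerate")
  dk[interior] <- abs(m[interior + 1L] - 2 * m[interior] + m[interior - 1L]) /
    s[interior]
  tab <- data.frame(k = ks, n_runs = as.integer(n_runs),
                    mean_loglik = as.numeric(m), sd_loglik = as.numeric(s),
                    delta_k = dk)
  list(table = tab, best_k = ks[interior][which.max(dk[interior])])
}
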