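#' Configuration for the structured diversity-panel simulator
#'
#' Defaults mirror a germplasm-collection survey: 62 accessions scored for
#' 603 genome-wide dominant markers, with two ancestral subpopulations and a
#' modest admixed fraction.
#'
#' @param n_accessions panel size.
#' @param n_markers dominant marker count.
#' @param k_subpop number of subpopulations (K >= 1).
#' @param freq_range range of ancestral band frequencies (uniform draw).
#' @param divergence half-width of the uniform perturbation each
#'   subpopulation applies to the ancestral frequency (bounded divergence).
#' @param admixture_level fraction of accessions receiving a mixed membership
#'   vector (symmetric Dirichlet) instead of a unit vector.
#' @param missing_rate per-call probability of a missing score.
#' @param seed RNG seed.
#' @return list of class `"panel_sim_config"`.
#' @export
panel_sim_config <- function(n_accessions = 62L, n_markers = 603L,
                             k_subpop = 2L, freq_range = c(0.05, 0.95),
                             divergence = 0.3, admixture_level = 0.2,
                             missing_rate = 0.01, seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_markers = as.integer(n_markers),
              k_subpop = as.integer(k_subpop),
              freq_range = freq_range, divergence = divergence,
              admixture_level = admixture_level,
              missing_rate = missing_rate, seed = as.integer(seed))
  if (cfg$k_subpop < 1L) stop("k_subpop must be >= 1")
  if (cfg$k_subpop > cfg$n_accessions)
    stop("k_subpop cannot exceed n_accessions")
  if (any(cfg$freq_range < 0) || any(cfg$freq_range > 1) ||
      diff(cfg$freq_range) < 0)
    stop("freq_range must be an increasing pair in [0,1]")
  if (cfg$divergence < 0 || cfg$divergence > 1)
    stop("divergence must lie in [0,1]")
  if (cfg$admixture_level < 0 || cfg$admixture_level > 1)
    stop("admixture_level must lie in [0,1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0,1)")
  class(cfg) <- "panel_sim_config"
  cfg
}

#' Simulate a structured diversity panel of dominant markers
#'
#' Hierarchical band-frequency model: each marker draws an ancestral band
#' frequency, each subpopulation perturbs it by a bounded uniform divergence
#' (clamped to \[0.01, 0.99\]), and each accession's band-presence probability
#' is its membership-weighted mixture of subpopulation frequencies. Calls are
#' Bernoulli draws, then thinned to missing at `missing_rate`.
#'
#' @param config a [panel_sim_config()].
#' @return list with `matrix` (a [marker_matrix()]), `memberships`
#'   (accessions x K matrix of truth membership weights, rows summing to 1)
#'   and `subpop_freq` (K x markers band frequencies).
#' @export
simulate_diversity_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  K <- config$k_subpop
  p0 <- stats::runif(config$n_markers, config$freq_range[1], config$freq_range[2])
  P <- matrix(NA_real_, K, config$n_markers)
  for (k in seq_len(K))
    P[k, ] <- pmin(pmax(p0 + stats::runif(config$n_markers, -config$divergence,
                                          config$divergence), 0.01), 0.99)
  # memberships: round-robin home subpopulation, an admixed subset gets
  # a symmetric Dirichlet vector (gamma normalisation)
  Q <- matrix(0, config$n_accessions, K)
  home <- rep_len(seq_len(K), config$n_accessions)
  Q[cbind(seq_len(config$n_accessions), home)] <- 1
  n_adm <- round(config$admixture_level * config$n_accessions)
  if (n_adm > 0 && K > 1L) {
    adm <- sample(config$n_accessions, n_adm)
    g <- matrix(stats::rgamma(n_adm * K, shape = 1), n_adm, K)
    Q[adm, ] <- g / rowSums(g)
  }
  prob <- Q %*% P
  calls <- matrix(as.integer(stats::runif(length(prob)) < prob),
                  nrow(prob), ncol(prob))
  if (config$missing_rate > 0)
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  dimnames(calls) <- list(sprintf("acc_%03d", seq_len(config$n_accessions)),
                          sprintf("dart_%04d", seq_len(config$n_markers)))
  rownames(Q) <- rownames(calls)
  list(matrix = marker_matrix(calls), memberships = Q, subpop_freq = P)
}

#' Simulate model-selection log-likelihood curves
#'
#' Emulates replicate runs of a model-based clustering program across a range
#' of assumed subpopulation counts K: the mean log-probability rises steeply
#' up to the true K and then plateaus (piecewise-linear mean), with Gaussian
#' replicate noise. Intended substrate for the [delta_k()] statistic.
#'
#' @param true_k location of the knee; must lie strictly inside `k_range`.
#' @param k_range integer vector of consecutive K values.
#' @param replicates runs per K (>= 2; default 20).
#' @param noise_sd replicate standard deviation of the log-probability.
#' @param seed RNG seed.
#' @param slope_before,slope_after mean log-probability gain per unit K
#'   before and after the knee.
#' @param base mean log-probability at the smallest K.
#' @return data frame with columns `k`, `replicate`, `loglik`.
#' @export
simulate_loglik_curves <- function(true_k, k_range = 1:10, replicates = 20L,
                                   noise_sd = 5, seed = 1L,
                                   slope_before = 100, slope_after = 5,
                                   base = -5000) {
  k_range <- sort(as.integer(k_range))
  if (!all(diff(k_range) == 1L)) stop("k_range must be consecutive integers")
  if (!(true_k > min(k_range) && true_k < max(k_range)))
    stop("true_k must lie strictly inside k_range")
  if (replicates < 2L) stop("need >= 2 replicates per K (sd undefined otherwise)")
  set.seed(seed)
  mean_l <- base + slope_before * pmin(k_range - k_range[1L], true_k - k_range[1L]) +
    slope_after * pmax(k_range - true_k, 0)
  out <- expand.grid(replicate = seq_len(replicates), k = k_range)[, 2:1]
  out$loglik <- mean_l[match(out$k, k_range)] +
    stats::rnorm(nrow(out), 0, noise_sd)
  out
}
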