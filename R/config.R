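#' Analysis configuration with study defaults
#'
#' Bundles the thresholds shared across the filtering cascade, linkage and
#' diversity analyses. Defaults are the values used throughout the package's
#' reference workflow: simplex segregation test at alpha 0.001, multiplex at
#' 0.01, at most 10% missing progeny calls, minimum allele row sum (read
#' depth) 600, redundancy similarity 0.99, LOD grouping threshold 5, 1,000
#' bootstrap replicates and restriction-site length 6 (PstI).
#'
#' @param seed integer RNG seed recorded with all stochastic output.
#' @param alpha_simplex significance level below which the simplex ratio is
#'   rejected.
#' @param alpha_multiplex significance level for the multiplex ratio tests.
#' @param max_missing_fraction maximum tolerated fraction of missing progeny
#'   calls per allele.
#' @param min_row_sum minimum read-count row sum for intercross alleles.
#' @param similarity_threshold pairwise call similarity above which alleles
#'   are collapsed as redundant.
#' @param lod_threshold LOD above which marker pairs are linked when grouping.
#' @param bootstrap_replicates bootstrap resamples for clade support.
#' @param restriction_site_length recognition-site length r used in the
#'   Nei-Li fragment distance.
#' @return a named list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       alpha_simplex = 0.001,
                       alpha_multiplex = 0.01,
                       max_missing_fraction = 0.10,
                       min_row_sum = 600,
                       similarity_threshold = 0.99,
                       lod_threshold = 5,
                       bootstrap_replicates = 1000L,
                       restriction_site_length = 6L) {
  cfg <- list(seed = as.integer(seed),
              alpha_simplex = alpha_simplex,
              alpha_multiplex = alpha_multiplex,
              max_missing_fraction = max_missing_fraction,
              min_row_sum = min_row_sum,
              similarity_threshold = similarity_threshold,
              lod_threshold = lod_threshold,
              bootstrap_replicates = as.integer(bootstrap_replicates),
              restriction_site_length = restriction_site_length)
  for (k in c("alpha_simplex", "alpha_multiplex", "max_missing_fraction",
              "similarity_threshold"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L ||
        is.na(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1)
      stop(sprintf("config value '%s' must be a probability in (0,1), got %s",
                   k, format(cfg[[k]])))
  for (k in c("min_row_sum", "lod_threshold", "restriction_site_length"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L ||
        is.na(cfg[[k]]) || cfg[[k]] <= 0)
      stop(sprintf("config value '%s' must be positive, got %s",
                   k, format(cfg[[k]])))
  if (is.na(cfg$bootstrap_replicates) || cfg$bootstrap_replicates < 0L)
    stop("config value 'bootstrap_replicates' must be >= 0")
  if (is.na(cfg$seed)) stop("config value 'seed' must be an integer")
  class(cfg) <- "run_config"
  cfg
}

#' Load a configuration file
#'
#' Reads a flat YAML (or `key: value`) file; absent keys fall back to the
#' [run_config()] defaults, unknown keys are an error.
#'
#' @param path path to a YAML file; an empty file yields all defaults.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must be a flat key: value mapping")
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
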