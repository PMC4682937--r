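#' Configuration for the octoploid F1 cross simulator
#'
#' Marker counts are given per dosage class under disomic inheritance:
#' single-dose (simplex) markers heterozygous in one parent segregate 1:1
#' (testcross), simplex markers heterozygous in both parents segregate 3:1
#' (intercross), duplex markers (two independent simplex doses in one parent,
#' on different sub-genomes) segregate 3:1 with a (1,0) parental pattern, and
#' triplex markers 7:1. Per-allele read depth ("row sum") follows a lognormal
#' model independent of genotype.
#'
#' @param n_progeny F1 population size (default 94).
#' @param n_simplex_p1,n_simplex_p2 testcross marker counts per parent.
#' @param n_intercross simplex markers heterozygous in both parents.
#' @param n_duplex,n_triplex multiplex marker counts (carried by parent 1).
#' @param n_linkage_groups chromosome-pair count to scatter simplex markers
#'   over (per parent).
#' @param map_length_cm linkage-group length(s) in centimorgans, recycled.
#' @param missing_rate per-call probability of a missing score.
#' @param error_rate per-call probability of a symmetric 0/1 flip.
#' @param depth_log_mean,depth_log_sd lognormal parameters of the per-allele
#'   row sum.
#' @param seed RNG seed.
#' @return list of class `"cross_sim_config"`.
#' @export
cross_sim_config <- function(n_progeny = 94L,
                             n_simplex_p1 = 180L, n_simplex_p2 = 150L,
                             n_intercross = 170L,
                             n_duplex = 60L, n_triplex = 30L,
                             n_linkage_groups = 5L, map_length_cm = 80,
                             missing_rate = 0.10, error_rate = 0.01,
                             depth_log_mean = 5.9, depth_log_sd = 0.8,
                             seed = 1L) {
  cfg <- list(n_progeny = as.integer(n_progeny),
              n_simplex_p1 = as.integer(n_simplex_p1),
              n_simplex_p2 = as.integer(n_simplex_p2),
              n_intercross = as.integer(n_intercross),
              n_duplex = as.integer(n_duplex),
              n_triplex = as.integer(n_triplex),
              n_linkage_groups = as.integer(n_linkage_groups),
              map_length_cm = map_length_cm,
              missing_rate = missing_rate, error_rate = error_rate,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              seed = as.integer(seed))
  if (cfg$n_progeny < 1L) stop("n_progeny must be >= 1")
  total <- cfg$n_simplex_p1 + cfg$n_simplex_p2 + cfg$n_intercross +
    cfg$n_duplex + cfg$n_triplex
  if (total <= 0L) stop("dosage-class marker counts sum to 0")
  if (any(c(cfg$missing_rate, cfg$error_rate) < 0) ||
      any(c(cfg$missing_rate, cfg$error_rate) >= 1))
    stop("missing_rate and error_rate must lie in [0,1)")
  if (any(cfg$map_length_cm <= 0)) stop("map lengths must be > 0")
  if (cfg$n_linkage_groups < 1L) stop("n_linkage_groups must be >= 1")
  class(cfg) <- "cross_sim_config"
  cfg
}

#' Simulate gamete inheritance along one linkage group
#'
#' For one parent and one chromosome pair, draws which of the two homologues
#' each progeny inherits at each marker position, with recombination between
#' adjacent positions given by the Haldane map function (no interference).
#'
#' @param positions_cm nondecreasing marker positions in cM.
#' @param n number of meioses (progeny).
#' @return n x length(positions_cm) matrix of homologue indicators (0/1);
#'   columns at identical positions are identical.
#' @export
simulate_meioses <- function(positions_cm, n) {
  m <- length(positions_cm)
  stopifnot(m >= 1L, !is.unsorted(positions_cm))
  H <- matrix(0L, n, m)
  H[, 1L] <- as.integer(stats::runif(n) < 0.5)
  if (m > 1L) {
    rf <- 0.5 * (1 - exp(-2 * diff(positions_cm) / 100))
    for (j in 2L:m) {
      switch_ <- stats::runif(n) < rf[j - 1L]
      H[, j] <- ifelse(switch_, 1L - H[, j - 1L], H[, j - 1L])
    }
  }
  H
}

#' Simulate an octoploid F1 mapping population
#'
#' Generates parental and progeny presence/absence calls for a pseudo-testcross
#' F1 under strict disomic inheritance. Simplex markers (testcross and
#' intercross) are placed on linkage groups and recombine per Haldane on their
#' cM positions; each dose is phased at random onto one of the two homologues.
#' Duplex and triplex markers are simulated as 2 or 3 independent unlinked
#' doses in parent 1. Symmetric genotyping errors and missing calls are
#' applied last, to parents and progeny alike; per-allele read depth is drawn
#' from the lognormal model.
#'
#' Before error and missingness, progeny band-presence fractions converge to
#' 1/2 (testcross), 3/4 (intercross and duplex) and 7/8 (triplex).
#'
#' @param config a [cross_sim_config()].
#' @return list of class `"f1_population"` with elements `parents` (2 x M
#'   matrix, rows `P1`/`P2`), `progeny` (a [marker_matrix()]), `row_sum`
#'   (named numeric depth per allele), `truth` (data frame: marker, class,
#'   parent, lg, cm, phase) and `config`.
#' @export
simulate_octoploid_cross <- function(config = cross_sim_config()) {
  stopifnot(inherits(config, "cross_sim_config"))
  set.seed(config$seed)
  n <- config$n_progeny
  lens <- rep_len(config$map_length_cm, config$n_linkage_groups)

  ids <- c(sprintf("tcP1_%04d", seq_len(config$n_simplex_p1)),
           sprintf("tcP2_%04d", seq_len(config$n_simplex_p2)),
           sprintf("ic_%04d",   seq_len(config$n_intercross)),
           sprintf("dup_%04d",  seq_len(config$n_duplex)),
           sprintf("tri_%04d",  seq_len(config$n_triplex)))
  cls <- rep(c("simplex_testcross_P1", "simplex_testcross_P2",
               "simplex_intercross", "duplex", "triplex"),
             c(config$n_simplex_p1, config$n_simplex_p2, config$n_intercross,
               config$n_duplex, config$n_triplex))
  M <- length(ids)
  truth <- data.frame(marker = ids, class = cls,
                      parent = c("P1", "P2", "both", "P1", "P1")[
                        match(cls, c("simplex_testcross_P1",
                                     "simplex_testcross_P2",
                                     "simplex_intercross", "duplex",
                                     "triplex"))],
                      lg = NA_integer_, cm = NA_real_,
                      phase = NA_integer_, stringsAsFactors = FALSE)

  linked <- cls %in% c("simplex_testcross_P1", "simplex_testcross_P2",
                       "simplex_intercross")
  nl <- sum(linked)
  if (nl) {
    truth$lg[linked] <- sample(rep_len(seq_len(config$n_linkage_groups), nl))
    truth$cm[linked] <- stats::runif(nl) * lens[truth$lg[linked]]
    truth$phase[linked] <- as.integer(stats::runif(nl) < 0.5)
  }

  prog <- matrix(0L, n, M, dimnames = list(sprintf("F1_%03d", seq_len(n)), ids))
  # per parent, per LG: one meiosis chain shared by that parent's doses there
  phase2 <- as.integer(stats::runif(sum(cls == "simplex_intercross")) < 0.5)
  names(phase2) <- ids[cls == "simplex_intercross"]
  for (parent in 1:2) {
    carries <- if (parent == 1L)
      cls %in% c("simplex_testcross_P1", "simplex_intercross")
    else
      cls %in% c("simplex_testcross_P2", "simplex_intercross")
    for (g in seq_len(config$n_linkage_groups)) {
      sel <- which(carries & truth$lg == g)
      if (!length(sel)) next
      sel <- sel[order(truth$cm[sel], ids[sel])]
      H <- simulate_meioses(truth$cm[sel], n)
      ph <- if (parent == 1L) truth$phase[sel] else
        ifelse(cls[sel] == "simplex_intercross", phase2[ids[sel]],
               truth$phase[sel])
      got <- sweep(H, 2L, ph, `==`)  # inherited the carrying homologue
      ic <- cls[sel] == "simplex_intercross"
      prog[, sel[!ic]] <- got[, !ic, drop = FALSE] * 1L
      if (any(ic))   # band present if received from either parent
        prog[, sel[ic]] <- pmax(prog[, sel[ic], drop = FALSE],
                                got[, ic, drop = FALSE] * 1L)
    }
  }
  for (k in which(cls == "duplex"))
    prog[, k] <- as.integer(stats::runif(n) < 0.5 | stats::runif(n) < 0.5)
  for (k in which(cls == "triplex"))
    prog[, k] <- as.integer(stats::runif(n) < 0.5 | stats::runif(n) < 0.5 |
                              stats::runif(n) < 0.5)

  parents <- rbind(P1 = as.integer(truth$parent %in% c("P1", "both")),
                   P2 = as.integer(truth$parent %in% c("P2", "both")))
  colnames(parents) <- ids

  flip <- function(x, rate) {
    if (rate > 0) {
      hit <- stats::runif(length(x)) < rate
      x[hit] <- 1L - x[hit]
    }
    x
  }
  drop <- function(x, rate) {
    if (rate > 0) x[stats::runif(length(x)) < rate] <- NA_integer_
    x
  }
  prog[] <- drop(flip(prog, config$error_rate), config$missing_rate)
  parents[] <- drop(flip(parents, config$error_rate), config$missing_rate)

  row_sum <- stats::rlnorm(M, config$depth_log_mean, config$depth_log_sd)
  names(row_sum) <- ids

  structure(list(parents = parents,
                 progeny = marker_matrix(prog),
                 row_sum = row_sum, truth = truth, config = config),
            class = "f1_population")
}

#' @export
print.f1_population <- function(x, ...) {
  cat(sprintf("f1_population: %d progeny x %d allele scorings\n",
              nrow(x$progeny), ncol(x$progeny)))
  print(table(x$truth$class))
  invisible(x)
}
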