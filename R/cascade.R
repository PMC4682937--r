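#' Stage-by-stage report of the allele filtering cascade
#'
#' Reconciles the counts of every stage of the single-dose marker selection
#' cascade and derives the shares on their conventional denominators, each
#' rounded to one decimal: monomorphic, missing-excluded and remaining as a
#' percentage of all allele scorings; multiplex and distorted as a percentage
#' of the alleles entering segregation testing; testcross (total and per
#' parent) and intercross shares of the simplex alleles; and the final
#' selection as a percentage of the SNP count (= allele scorings / 2).
#'
#' @param total_alleles binary allele scorings entering the cascade.
#' @param monomorphic alleles monomorphic in the progeny.
#' @param excluded_missing alleles removed for missing data or uninformative
#'   parents.
#' @param multiplex alleles fitting a multiplex ratio.
#' @param distorted alleles fitting no tested ratio.
#' @param testcross_p1,testcross_p2 simplex testcross alleles heterozygous in
#'   parent 1 (female) and parent 2 (male).
#' @param intercross_lowdepth intercross alleles removed by the row-sum filter.
#' @param redundant alleles collapsed as redundant (informational; the
#'   selected count precedes this collapse).
#' @param n_snps SNP count; defaults to `total_alleles / 2`.
#' @return list of class `"cascade_report"` with all stage counts, the
#'   derived `remaining`, `simplex_total`, `testcross_total`,
#'   `intercross_total`, `intercross_kept` and `final_selected`, and a `pct`
#'   sub-list of one-decimal percentages.
#' @export
cascade_report <- function(total_alleles, monomorphic, excluded_missing,
                           multiplex, distorted,
                           testcross_p1, testcross_p2,
                           intercross_lowdepth, redundant = 0L,
                           n_snps = total_alleles / 2) {
  remaining <- total_alleles - monomorphic - excluded_missing
  simplex_total <- remaining - multiplex - distorted
  testcross_total <- testcross_p1 + testcross_p2
  intercross_total <- simplex_total - testcross_total
  intercross_kept <- intercross_total - intercross_lowdepth
  final_selected <- testcross_total + intercross_kept
  if (min(remaining, simplex_total, intercross_total, intercross_kept) < 0)
    stop("stage counts do not reconcile: a derived count is negative")
  pct1 <- function(num, den) round(100 * num / den, 1)
  rep <- list(total_alleles = total_alleles, monomorphic = monomorphic,
              excluded_missing = excluded_missing, remaining = remaining,
              multiplex = multiplex, distorted = distorted,
              simplex_total = simplex_total,
              testcross_p1 = testcross_p1, testcross_p2 = testcross_p2,
              testcross_total = testcross_total,
              intercross_total = intercross_total,
              intercross_lowdepth = intercross_lowdepth,
              intercross_kept = intercross_kept,
              redundant = redundant,
              final_selected = final_selected,
              final_after_redundancy = final_selected - redundant,
              n_snps = n_snps,
              pct = list(
                monomorphic = pct1(monomorphic, total_alleles),
                excluded_missing = pct1(excluded_missing, total_alleles),
                remaining = pct1(remaining, total_alleles),
                multiplex = pct1(multiplex, remaining),
                distorted = pct1(distorted, remaining),
                testcross = pct1(testcross_total, simplex_total),
                testcross_p1 = pct1(testcross_p1, simplex_total),
                testcross_p2 = pct1(testcross_p2, simplex_total),
                intercross = pct1(intercross_total, simplex_total),
                final_selected = pct1(final_selected, n_snps)))
  class(rep) <- "cascade_report"
  rep
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("allele filtering cascade:\n")
  fmt <- function(lbl, n, p = NULL)
    cat(sprintf("  %-28s %6d%s\n", lbl, n,
                if (is.null(p)) "" else sprintf(" (%.1f%%)", p)))
  fmt("allele scorings", x$total_alleles)
  fmt("monomorphic", x$monomorphic, x$pct$monomorphic)
  fmt("missing/parent excluded", x$excluded_missing, x$pct$excluded_missing)
  fmt("remaining", x$remaining, x$pct$remaining)
  fmt("multiplex", x$multiplex, x$pct$multiplex)
  fmt("distorted", x$distorted, x$pct$distorted)
  fmt("simplex", x$simplex_total)
  fmt("  testcross P1", x$testcross_p1, x$pct$testcross_p1)
  fmt("  testcross P2", x$testcross_p2, x$pct$testcross_p2)
  fmt("  intercross", x$intercross_total, x$pct$intercross)
  fmt("intercross kept (depth)", x$intercross_kept)
  fmt("selected", x$final_selected, x$pct$final_selected)
  fmt("after redundancy collapse", x$final_after_redundancy)
  invisible(x)
}

#' Run the full allele filtering and classification cascade
#'
#' Applies, in order: the monomorphic filter, the missing-data/parental
#' filter, chi-square segregation classification, the read-depth (row-sum)
#' filter on intercross alleles, and the redundancy collapse on the selected
#' set. At every stage kept + removed partitions the input exactly.
#'
#' @param pop an `f1_population`.
#' @param config a [run_config()] supplying the thresholds.
#' @param snp_of optional named vector mapping allele ID to SNP of origin,
#'   for the complementary-allele redundancy rule.
#' @return list with `report` (a [cascade_report()]), `classes` (the
#'   classification data frame, augmented with the exclusion stages), and
#'   `selected` (final [marker_matrix()] after redundancy collapse).
#' @export
run_cascade <- function(pop, config = run_config(), snp_of = NULL) {
  all_ids <- colnames(pop$progeny)
  st1 <- filter_monomorphic(pop, all_ids)
  st2 <- filter_missing(pop, config$max_missing_fraction, st1$kept)
  cls <- classify_segregation(pop, st2$kept,
                              alpha_simplex = config$alpha_simplex,
                              alpha_multiplex = config$alpha_multiplex)
  ic <- cls$marker[cls$class == "simplex_intercross"]
  st4 <- if (length(ic)) filter_rowsum(pop, ic, config$min_row_sum)
         else list(kept = character(0), excluded_rowsum = character(0))
  tc1 <- cls$marker[cls$class == "simplex_testcross_P1"]
  tc2 <- cls$marker[cls$class == "simplex_testcross_P2"]
  selected <- c(tc1, tc2, st4$kept)
  st5 <- if (length(selected))
    collapse_redundant(pop, selected, config$similarity_threshold,
                       snp_of = snp_of)
  else list(kept = character(0), excluded_redundant = character(0))

  classes <- data.frame(marker = all_ids, class = NA_character_,
                        stringsAsFactors = FALSE)
  classes$class[all_ids %in% st1$monomorphic] <- "monomorphic"
  classes$class[all_ids %in% st2$excluded_missing] <- "excluded_missing"
  classes$class[match(cls$marker, all_ids)] <- cls$class
  classes$class[all_ids %in% st4$excluded_rowsum] <- "excluded_rowsum"
  classes$class[all_ids %in% st5$excluded_redundant] <- "excluded_redundant"
  stopifnot(!anyNA(classes$class))

  report <- cascade_report(
    total_alleles = length(all_ids),
    monomorphic = length(st1$monomorphic),
    excluded_missing = length(st2$excluded_missing),
    multiplex = sum(cls$class == "multiplex"),
    distorted = sum(cls$class == "distorted"),
    testcross_p1 = length(tc1), testcross_p2 = length(tc2),
    intercross_lowdepth = length(st4$excluded_rowsum),
    redundant = length(st5$excluded_redundant))
  list(report = report, classes = classes, chisq = cls,
       selected = marker_matrix(unclass(pop$progeny)[, st5$kept, drop = FALSE]))
}
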