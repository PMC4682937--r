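#' Two-row-per-SNP allele scoring table
#'
#' Sequencing-derived SNPs in a polyploid are scored as two binary allele
#' rows (reference allele, SNP allele) so that alleles can be filtered
#' independently without confounding sub-genomes. Rows are allele scorings,
#' columns accessions.
#'
#' @param scores matrix with 2 rows per SNP, values in \{0,1,NA\}.
#' @param snp_ids character vector, one per SNP (rows 2k-1, 2k belong to SNP k).
#' @param row_sum optional nonnegative read-count total per allele row.
#' @param clone_seq optional clone sequence per SNP.
#' @return list of class `"snp_allele_table"`.
#' @export
snp_allele_table <- function(scores, snp_ids, row_sum = NULL, clone_seq = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) %% 2L != 0L)
    stop("allele scoring table must have an even row count (2 rows per SNP)")
  if (length(snp_ids) != nrow(scores) / 2L)
    stop("snp_ids length must be half the allele row count (mismatched row pairing)")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP IDs")
  if (!is.null(row_sum)) {
    if (length(row_sum) != nrow(scores)) stop("row_sum needs one value per allele row")
    if (any(row_sum < 0, na.rm = TRUE)) stop("row_sum must be nonnegative")
  }
  structure(list(scores = scores, snp_ids = as.character(snp_ids),
                 row_sum = row_sum, clone_seq = clone_seq),
            class = "snp_allele_table")
}

#' Expand SNPs into binary allele scorings
#'
#' Each SNP contributes two allele scorings, identified as `<snp>_ref` and
#' `<snp>_snp`; output marker count is exactly twice the SNP count.
#'
#' @param snps a [snp_allele_table()].
#' @return a [marker_matrix()] (accessions x alleles) with, if present, the
#'   depth attached as `attr(, "row_sum")` and the SNP of origin as
#'   `attr(, "snp_of")` (named character vector).
#' @export
expand_alleles <- function(snps) {
  stopifnot(inherits(snps, "snp_allele_table"))
  s <- nrow(snps$scores) / 2L
  allele_ids <- as.vector(rbind(paste0(snps$snp_ids, "_ref"),
                                paste0(snps$snp_ids, "_snp")))
  acc <- colnames(snps$scores)
  if (is.null(acc)) acc <- paste0("acc", seq_len(ncol(snps$scores)))
  m <- marker_matrix(t(snps$scores), accession_ids = acc,
                     marker_ids = allele_ids)
  if (!is.null(snps$row_sum)) {
    rs <- snps$row_sum
    names(rs) <- allele_ids
    attr(m, "row_sum") <- rs
  }
  snp_of <- rep(snps$snp_ids, each = 2L)
  names(snp_of) <- allele_ids
  attr(m, "snp_of") <- snp_of
  m
}

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Tests observed presence/absence progeny counts against an expected a:b
#' ratio (presence:absence) with the classical 1-df chi-square statistic, no
#' continuity correction.
#'
#' @param present,absent observed progeny counts.
#' @param ratio length-2 numeric `c(a, b)`, expected presence:absence.
#' @return list with `statistic`, `df` (= 1), `p_value`, `tested_ratio`.
#' @export
chi_square_gof <- function(present, absent, ratio) {
  n <- present + absent
  if (n <= 0) stop("no scored progeny (present + absent = 0)")
  if (any(ratio <= 0) || length(ratio) != 2L)
    stop("ratio must be two positive numbers a:b")
  expd <- n * ratio / sum(ratio)
  stat <- sum((c(present, absent) - expd)^2 / expd)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       tested_ratio = paste0(ratio[1], ":", ratio[2]))
}

#' Partition alleles into polymorphic and monomorphic
#'
#' An allele scoring is monomorphic when all non-missing progeny calls are
#' equal (an all-missing column is not monomorphic; the missing-data filter
#' handles it).
#'
#' @param pop an `f1_population` (or any list with a `progeny` marker matrix).
#' @param markers optional subset of allele IDs to consider.
#' @return list with character vectors `kept` and `monomorphic`.
#' @export
filter_monomorphic <- function(pop, markers = colnames(pop$progeny)) {
  X <- pop$progeny[, markers, drop = FALSE]
  n1 <- colSums(X == 1L, na.rm = TRUE)
  n0 <- colSums(X == 0L, na.rm = TRUE)
  mono <- (n1 == 0L | n0 == 0L) & (n1 + n0 > 0L)
  list(kept = markers[!mono], monomorphic = markers[mono])
}

#' Exclude alleles with excessive missing data or uninformative parents
#'
#' An allele is excluded when more than `floor(max_missing_fraction * n)`
#' progeny are missing, when either parental call is missing, or when both
#' parents score 0 (the band cannot have been inherited).
#'
#' @param pop an `f1_population`.
#' @param max_missing_fraction maximum tolerated missing fraction (default 0.10).
#' @param markers optional subset of allele IDs.
#' @return list with character vectors `kept` and `excluded_missing`.
#' @export
filter_missing <- function(pop, max_missing_fraction = 0.10,
                           markers = colnames(pop$progeny)) {
  X <- pop$progeny[, markers, drop = FALSE]
  n <- nrow(X)
  miss <- colSums(is.na(X))
  p1 <- pop$parents["P1", markers]
  p2 <- pop$parents["P2", markers]
  bad <- miss > floor(max_missing_fraction * n) | is.na(p1) | is.na(p2) |
    (!is.na(p1) & !is.na(p2) & p1 == 0L & p2 == 0L)
  list(kept = markers[!bad], excluded_missing = markers[bad])
}

#' Disomic multiplex segregation ratios per parental pattern
#'
#' Presence:absence ratios for 2-3 dose (duplex/triplex) markers under
#' disomic inheritance, keyed by the parental presence pattern. A marker
#' present in one parent only can be duplex (3:1) or triplex (7:1) in that
#' parent; one present in both parents can combine doses for 7:1, 13:3 or
#' 15:1.
#'
#' @return named list: `"10"`, `"01"`, `"11"`, each a list of `c(a, b)` ratios.
#' @export
multiplex_ratios <- function() {
  one_parent <- list(c(3, 1), c(7, 1))
  list("10" = one_parent, "01" = one_parent,
       "11" = list(c(7, 1), c(13, 3), c(15, 1)))
}

#' Classify allele segregation in a pseudo-testcross F1
#'
#' For each allele, the expected simplex ratio follows from the parental
#' presence pattern: present in one parent only implies a 1:1 testcross,
#' present in both a 3:1 intercross. If the chi-square test does not reject
#' the simplex ratio at `alpha_simplex`, the allele is classified simplex
#' (testcross P1/P2 or intercross per pattern). Otherwise the multiplex
#' ratios consistent with the pattern are tried; if any fits at
#' `alpha_multiplex` the allele is multiplex, else distorted.
#'
#' @param pop an `f1_population`.
#' @param markers allele IDs to classify (should already have passed the
#'   monomorphic and missing-data filters).
#' @param alpha_simplex rejection level for the simplex ratio (default 0.001).
#' @param alpha_multiplex acceptance level for multiplex ratios (default 0.01).
#' @param ratios multiplex ratio set, as [multiplex_ratios()].
#' @return data frame: `marker`, `class`, `pattern`, `statistic`, `p_value`,
#'   `tested_ratio` (the accepted ratio, or the simplex ratio if distorted).
#' @export
classify_segregation <- function(pop, markers = colnames(pop$progeny),
                                 alpha_simplex = 0.001,
                                 alpha_multiplex = 0.01,
                                 ratios = multiplex_ratios()) {
  X <- pop$progeny[, markers, drop = FALSE]
  p1 <- pop$parents["P1", markers]
  p2 <- pop$parents["P2", markers]
  out <- data.frame(marker = markers, class = NA_character_,
                    pattern = paste0(p1, p2), statistic = NA_real_,
                    p_value = NA_real_, tested_ratio = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(markers)) {
    if (is.na(p1[i]) || is.na(p2[i]) || (p1[i] == 0L && p2[i] == 0L))
      stop("allele ", markers[i],
           " has an uninformative parental pattern; run filter_missing first")
    pat <- paste0(p1[i], p2[i])
    pres <- sum(X[, i] == 1L, na.rm = TRUE)
    abst <- sum(X[, i] == 0L, na.rm = TRUE)
    simplex_ratio <- if (pat == "11") c(3, 1) else c(1, 1)
    ts <- chi_square_gof(pres, abst, simplex_ratio)
    if (ts$p_value >= alpha_simplex) {
      out$class[i] <- switch(pat, "10" = "simplex_testcross_P1",
                             "01" = "simplex_testcross_P2",
                             "11" = "simplex_intercross")
      out$statistic[i] <- ts$statistic
      out$p_value[i] <- ts$p_value
      out$tested_ratio[i] <- ts$tested_ratio
    } else {
      fits <- lapply(ratios[[pat]], function(r) chi_square_gof(pres, abst, r))
      ps <- vapply(fits, `[[`, 0, "p_value")
      best <- which.max(ps)
      if (ps[best] >= alpha_multiplex) {
        out$class[i] <- "multiplex"
        out$statistic[i] <- fits[[best]]$statistic
        out$p_value[i] <- ps[best]
        out$tested_ratio[i] <- fits[[best]]$tested_ratio
      } else {
        out$class[i] <- "distorted"
        out$statistic[i] <- ts$statistic
        out$p_value[i] <- ts$p_value
        out$tested_ratio[i] <- ts$tested_ratio
      }
    }
  }
  out
}

#' Depth filter for intercross alleles
#'
#' Intercross (3:1) markers are less informative than testcross markers, so
#' only the most robustly sequenced ones are retained: those whose allele
#' row sum (total read count) reaches `min_row_sum`. Testcross alleles are
#' not touched by this filter.
#'
#' @param pop an `f1_population` (source of `row_sum`).
#' @param intercross_markers allele IDs classified `simplex_intercross`.
#' @param min_row_sum retention threshold (default 600; a row sum exactly at
#'   the threshold is kept).
#' @return list with character vectors `kept` and `excluded_rowsum`.
#' @export
filter_rowsum <- function(pop, intercross_markers, min_row_sum = 600) {
  rs <- pop$row_sum[intercross_markers]
  if (anyNA(rs) || length(rs) != length(intercross_markers)) {
    missing_rs <- intercross_markers[is.na(rs) |
                                       !(intercross_markers %in% names(pop$row_sum))]
    stop("row sum unavailable for allele(s): ",
         paste(utils::head(missing_rs, 5L), collapse = ", "))
  }
  keep <- rs >= min_row_sum
  list(kept = intercross_markers[keep],
       excluded_rowsum = intercross_markers[!keep])
}

#' Collapse redundant allele scorings
#'
#' Pairwise call similarity is the fraction of progeny, among those scored in
#' both alleles, with equal calls. Pairs above `similarity_threshold`, and
#' exactly complementary pairs arising from the two alleles of one SNP, are
#' collapsed to a single representative: the allele with fewer missing calls,
#' ties broken by lexicographic ID. Pairs sharing fewer than `min_overlap`
#' jointly scored progeny are skipped with a warning.
#'
#' @param pop an `f1_population`.
#' @param markers selected allele IDs.
#' @param similarity_threshold collapse above this similarity (default 0.99).
#' @param snp_of optional named vector mapping allele ID to SNP of origin
#'   (enables the complementary-allele rule).
#' @param min_overlap minimum jointly scored progeny for a reliable
#'   similarity (default 20).
#' @return list with `kept`, `excluded_redundant`, and the `similarity`
#'   matrix used.
#' @export
collapse_redundant <- function(pop, markers, similarity_threshold = 0.99,
                               snp_of = NULL, min_overlap = 20L) {
  if (!length(markers)) stop("selected allele set is empty")
  X <- pop$progeny[, markers, drop = FALSE]
  P <- (!is.na(X)) * 1
  A <- (X == 1L & !is.na(X)) * 1
  B <- (X == 0L & !is.na(X)) * 1
  overlap <- crossprod(P)
  eq <- crossprod(A) + crossprod(B)
  sim <- eq / overlap
  thin <- overlap < min_overlap
  diag(thin) <- FALSE
  if (any(thin)) {
    warning(sum(thin) / 2, " allele pair(s) share fewer than ", min_overlap,
            " scored progeny; similarity not assessed for them")
    sim[thin] <- NA_real_
  }
  m <- length(markers)
  link <- !is.na(sim) & sim > similarity_threshold
  if (!is.null(snp_of)) {
    # two alleles of one SNP with exactly complementary calls mark one locus
    comp <- (eq == 0) & (overlap >= min_overlap) &
      outer(snp_of[markers], snp_of[markers], `==`)
    link <- link | comp
  }
  diag(link) <- FALSE
  # union-find over linked pairs
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) for (j in which(link[i, ])) if (j > i) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp_id <- vapply(seq_len(m), find, 0L)
  miss_ct <- colSums(is.na(X))
  kept <- character(0)
  for (cid in unique(comp_id)) {
    members <- markers[comp_id == cid]
    ord <- order(miss_ct[members], members)
    kept <- c(kept, members[ord[1L]])
  }
  list(kept = sort(kept),
       excluded_redundant = sort(setdiff(markers, kept)),
       similarity = sim)
}
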