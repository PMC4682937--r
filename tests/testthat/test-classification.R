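# hand-built populations for exercising individual cascade stages
make_pop <- function(progeny, p1, p2, row_sum = NULL) {
  m <- marker_matrix(progeny)
  parents <- rbind(P1 = as.integer(p1), P2 = as.integer(p2))
  colnames(parents) <- colnames(m)
  if (is.null(row_sum)) row_sum <- stats::setNames(rep(1000, ncol(m)),
                                                   colnames(m))
  list(parents = parents, progeny = m, row_sum = row_sum)
}
col_of <- function(n1, n0, nNA = 0) c(rep(1L, n1), rep(0L, n0),
                                      rep(NA_integer_, nNA))

test_that("chi-square goodness of fit matches the closed-form 1-df tail", {
  # perfect 1:1 fit
  r0 <- chi_square_gof(47, 47, c(1, 1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # frozen worked examples
  r1 <- chi_square_gof(60, 34, c(1, 1))
  expect_equal(r1$statistic, 7.19148936, tolerance = 1e-8)
  expect_equal(r1$p_value, erfc_tail_p(r1$statistic), tolerance = 1e-10)
  expect_equal(r1$p_value, 0.007325016, tolerance = 1e-6)
  r2 <- chi_square_gof(70, 24, c(3, 1))
  expect_equal(r2$statistic, (70 - 70.5)^2 / 70.5 + (24 - 23.5)^2 / 23.5)
  expect_equal(r2$p_value, 0.9051975, tolerance = 1e-6)
  # oracle agreement over a statistic grid
  grid <- seq(0, 50, by = 0.25)
  p_impl <- pchisq(grid, df = 1, lower.tail = FALSE)
  expect_true(all(abs(p_impl - erfc_tail_p(grid)) < 1e-10))
  expect_error(chi_square_gof(0, 0, c(1, 1)), "present \\+ absent")
})

test_that("monomorphic filter keys on non-missing progeny calls only", {
  pop <- make_pop(cbind(allone = rep(1L, 10),
                        split = col_of(5, 5),
                        zeromiss = col_of(0, 7, 3),
                        allmiss = rep(NA_integer_, 10)),
                  p1 = c(1, 1, 1, 1), p2 = c(0, 0, 0, 0))
  part <- filter_monomorphic(pop)
  expect_setequal(part$monomorphic, c("allone", "zeromiss"))
  expect_setequal(part$kept, c("split", "allmiss"))
  expect_length(intersect(part$kept, part$monomorphic), 0)
})

test_that("missing-data filter applies the >10% and parental rules", {
  n <- 94
  pop <- make_pop(cbind(miss10 = col_of(44, 40, 10),
                        miss9 = col_of(45, 40, 9),
                        pmiss = col_of(50, 44),
                        p00 = col_of(50, 44),
                        clean = col_of(50, 44)),
                  p1 = c(1, 1, NA, 0, 1), p2 = c(0, 0, 1, 0, 0))
  part <- filter_missing(pop, 0.10)
  expect_setequal(part$excluded_missing, c("miss10", "pmiss", "p00"))
  expect_setequal(part$kept, c("miss9", "clean"))
})

test_that("segregation classes follow parental pattern then ratio fit", {
  pop <- make_pop(cbind(tc1 = col_of(47, 47),
                        tc2 = col_of(47, 47),
                        ic = col_of(70, 24),
                        dup = col_of(70, 24),
                        tri = col_of(82, 12),
                        dist = col_of(55, 39)),
                  p1 = c(1, 0, 1, 1, 1, 1),
                  p2 = c(0, 1, 1, 0, 0, 1))
  cls <- classify_segregation(pop)
  expect_equal(cls$class,
               c("simplex_testcross_P1", "simplex_testcross_P2",
                 "simplex_intercross", "multiplex", "multiplex", "distorted"))
  # the duplex call came from accepting 3:1 after rejecting 1:1
  expect_equal(cls$tested_ratio[cls$marker == "dup"], "3:1")
  expect_equal(cls$tested_ratio[cls$marker == "tri"], "7:1")
  expect_error(classify_segregation(make_pop(cbind(x = col_of(5, 5)),
                                             p1 = 0, p2 = 0)),
               "uninformative")
})

test_that("classification is invariant to progeny order and 0/1 relabeling", {
  pop <- make_pop(cbind(a = col_of(60, 30, 4), b = col_of(25, 65, 4)),
                  p1 = c(1, 1), p2 = c(1, 0))
  base <- classify_segregation(pop)
  set.seed(1)
  perm <- sample(nrow(pop$progeny))
  pop2 <- pop
  pop2$progeny <- marker_matrix(unclass(pop$progeny)[perm, , drop = FALSE])
  expect_equal(classify_segregation(pop2)[, -1], base[, -1])
  # flipping presence/absence together with the ratio orientation preserves
  # the chi-square statistic and p-value
  r <- chi_square_gof(60, 30, c(3, 1))
  rf <- chi_square_gof(30, 60, c(1, 3))
  expect_equal(r$statistic, rf$statistic)
  expect_equal(r$p_value, rf$p_value)
})

test_that("the non-simplex set grows monotonically with alpha_simplex", {
  pop <- simulate_octoploid_cross(cross_sim_config(
    n_simplex_p1 = 80, n_simplex_p2 = 80, n_intercross = 80, n_duplex = 80,
    n_triplex = 40, missing_rate = 0, error_rate = 0.02, seed = 13))
  keep <- filter_missing(pop, 0.10, filter_monomorphic(pop)$kept)$kept
  alphas <- c(1e-4, 1e-3, 1e-2, 0.05)
  nonsimplex <- vapply(alphas, function(a) {
    cls <- classify_segregation(pop, keep, alpha_simplex = a)
    sum(cls$class %in% c("multiplex", "distorted"))
  }, 0)
  # a marker leaves the simplex class exactly when p < alpha, so the
  # rejected set is nested as alpha rises
  expect_true(all(diff(nonsimplex) >= 0))
})

test_that("row-sum filter keeps depth >= 600 and touches only intercross", {
  pop <- make_pop(cbind(a = col_of(70, 24), b = col_of(70, 24),
                        c = col_of(47, 47)),
                  p1 = c(1, 1, 1), p2 = c(1, 1, 0),
                  row_sum = c(a = 600, b = 599, c = 10))
  part <- filter_rowsum(pop, c("a", "b"))
  expect_equal(part$kept, "a")
  expect_equal(part$excluded_rowsum, "b")
  expect_error(filter_rowsum(pop, c("a", "zzz")), "zzz")
})

test_that("redundancy collapse handles identity, near-misses and complements", {
  set.seed(5)
  base <- col_of(24, 70)[sample(94)]
  near <- base; near[1:3] <- 1L - near[1:3]       # similarity 91/94 ~ 0.968
  almost <- base; almost[1] <- 1L - almost[1]     # similarity 93/94 ~ 0.989
  pop <- make_pop(cbind(s1_ref = base, s1_snp = 1L - base,
                        s2_ref = base, s3_ref = near, s4_ref = almost),
                  p1 = rep(1, 5), p2 = rep(0, 5))
  snp_of <- c(s1_ref = "s1", s1_snp = "s1", s2_ref = "s2", s3_ref = "s3",
              s4_ref = "s4")
  out <- collapse_redundant(pop, colnames(pop$progeny), 0.99, snp_of = snp_of)
  # identical pair (s1_ref, s2_ref) and the complementary alleles of s1
  # collapse; 0.968 and 0.989 similarities stay below the threshold
  expect_setequal(out$kept, c("s1_ref", "s3_ref", "s4_ref"))
  expect_equal(out$similarity["s1_ref", "s2_ref"], 1)
  expect_lt(out$similarity["s1_ref", "s4_ref"], 0.99)
  # short overlap is refused
  tiny <- make_pop(cbind(x = col_of(3, 2), y = col_of(3, 2)),
                   p1 = c(1, 1), p2 = c(0, 0))
  expect_warning(collapse_redundant(tiny, c("x", "y")), "fewer than 20")
})

test_that("allele expansion doubles SNPs and rejects odd tables", {
  sc <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, NA), c(0, 0, 1))
  colnames(sc) <- c("accA", "accB", "accC")
  tbl <- snp_allele_table(sc, snp_ids = c("snp1", "snp2"),
                          row_sum = c(700, 650, 300, 200))
  m <- expand_alleles(tbl)
  expect_equal(ncol(m), 4L)
  expect_equal(colnames(m), c("snp1_ref", "snp1_snp", "snp2_ref", "snp2_snp"))
  expect_equal(unname(attr(m, "row_sum")["snp2_ref"]), 300)
  expect_equal(unname(attr(m, "snp_of")["snp2_snp"]), "snp2")
  expect_equal(unname(m["accC", "snp1_ref"]), 1L)
  expect_error(snp_allele_table(sc[1:3, ], "snp1"), "even row count")
  expect_error(snp_allele_table(sc, c("s1", "s2", "s3")), "mismatched")
})

test_that("cascade partitions reconcile at every stage on simulated data", {
  pop <- simulate_octoploid_cross(cross_sim_config(seed = 31))
  res <- run_cascade(pop, run_config())
  rep <- res$report
  expect_equal(rep$monomorphic + rep$excluded_missing + rep$remaining,
               rep$total_alleles)
  expect_equal(rep$multiplex + rep$distorted + rep$simplex_total,
               rep$remaining)
  expect_equal(rep$testcross_total + rep$intercross_total, rep$simplex_total)
  expect_equal(rep$intercross_kept + rep$intercross_lowdepth,
               rep$intercross_total)
  expect_equal(rep$final_selected, rep$testcross_total + rep$intercross_kept)
  expect_equal(ncol(res$selected), rep$final_after_redundancy)
  expect_equal(nrow(res$classes), rep$total_alleles)
  expect_false(anyNA(res$classes$class))
})

test_that("error-free simulated markers recover their true classes", {
  pop <- simulate_octoploid_cross(cross_sim_config(
    n_simplex_p1 = 250, n_simplex_p2 = 250, n_intercross = 250,
    n_duplex = 120, n_triplex = 120,
    missing_rate = 0, error_rate = 0, seed = 17))
  keep <- filter_missing(pop, 0.10, filter_monomorphic(pop)$kept)$kept
  cls <- classify_segregation(pop, keep)
  truth <- pop$truth$class[match(cls$marker, pop$truth$marker)]
  for (want in c("simplex_testcross_P1", "simplex_testcross_P2",
                 "simplex_intercross")) {
    hit <- mean(cls$class[truth == want] == want)
    expect_gte(hit, 0.99)
  }
  # duplex markers land in multiplex whenever the 1:1 test rejects
  dup <- cls[truth == "duplex", ]
  rejected <- vapply(dup$marker, function(mk) {
    x <- pop$progeny[, mk]
    chi_square_gof(sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE),
                   c(1, 1))$p_value < 0.001
  }, TRUE)
  expect_true(all(dup$class[rejected] == "multiplex"))
})
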