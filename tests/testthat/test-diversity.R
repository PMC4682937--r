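test_that("dominant-marker PIC is bounded, symmetric and maximal at 0.5", {
  expect_equal(pic_dominant(0.5), 0.5)
  expect_equal(pic_dominant(0), 0)
  expect_equal(pic_dominant(1), 0)
  expect_equal(pic_dominant(0.2), 0.32)
  f <- seq(0, 1, by = 0.001)
  expect_true(all(pic_dominant(f) >= 0 & pic_dominant(f) <= 0.5))
  expect_equal(pic_dominant(f), pic_dominant(1 - f))
  expect_error(pic_dominant(1.2))

  m <- marker_matrix(cbind(half = c(1L, 1L, 0L, 0L),
                           rare = c(1L, 0L, 0L, 0L),
                           gone = c(NA, NA, NA, NA)))
  s <- pic_summary(m)
  expect_equal(s$per_marker$pic[1], 0.5)
  expect_equal(s$per_marker$pic[2], 2 * 0.25 * 0.75)
  expect_true(is.na(s$per_marker$pic[3]))
  expect_equal(sum(s$bins), 100)
})

test_that("call rate and replicate reproducibility follow their contracts", {
  x <- marker_matrix(rbind(a = c(1L, 0L, 1L), a_rep = c(1L, 0L, 0L),
                           b = c(0L, NA, 1L), b_rep = c(0L, 1L, NA)))
  colnames(x) <- c("m1", "m2", "m3")
  q <- quality_metrics(x, replicate_pairs = cbind(c("a", "b"),
                                                  c("a_rep", "b_rep")))
  expect_equal(unname(q$call_rate), c(1, 3 / 4, 3 / 4))
  # m1: both pairs agree; m2/m3: one usable pair each (one-sided missing
  # comparisons are excluded), agreeing for m2 and discordant for m3
  expect_equal(unname(q$reproducibility), c(1, 1, 0))
  expect_equal(q$mean_reproducibility, 3 / 4)
  q0 <- quality_metrics(x)
  expect_null(q0$reproducibility)
  expect_true(is.na(q0$mean_reproducibility))
  expect_error(quality_metrics(x, cbind("a", "nope")), "unknown accession")
})

test_that("Nei-Li fragment distance solves the retention relation", {
  # F = 0.8: the solved G satisfies the fixed-point residual and D = -(2/r) ln G
  g <- solve_retention(0.8)
  expect_lt(abs(g^4 - 0.8 * (3 - 2 * g)), 1e-10)
  expect_equal(-(2 / 6) * log(g), -(1 / 3) * log(g))
  # limiting behaviour and missing-data handling
  x <- marker_matrix(rbind(A = c(1L, 1L, 0L, 1L, 0L),
                           B = c(1L, 1L, 0L, 1L, 0L),
                           C = c(0L, 0L, 1L, 0L, 1L),
                           D = c(1L, 0L, 1L, 1L, NA)))
  d <- nei_li_distance(x, r = 6)
  expect_equal(d$D["A", "B"], 0)
  expect_equal(d$F["A", "B"], 1)
  expect_true(d$saturated["A", "C"])       # disjoint band profiles
  expect_true(is.na(d$D["A", "C"]))
  expect_equal(max(abs(d$D - t(d$D)), na.rm = TRUE), 0)
  expect_equal(unname(diag(d$D)), rep(0, 4))
  # pairwise deletion: A~D computed over the 4 markers scored in both
  expect_equal(d$F["A", "D"], 2 * 2 / (3 + 3))
  # capping makes saturated pairs finite
  dc <- nei_li_distance(x, r = 6, cap = 5)
  expect_equal(dc$D["A", "C"], 5)

  # D decreases in F; doubling r halves D exactly
  fs <- seq(0.1, 0.99, by = 0.01)
  ds <- vapply(fs, function(f) -(2 / 6) * log(solve_retention(f)), 0)
  expect_true(all(diff(ds) < 0))
  x2 <- marker_matrix(rbind(A = c(1L, 1L, 0L, 1L), B = c(1L, 0L, 1L, 1L),
                            C = c(0L, 1L, 1L, 0L)))
  expect_equal(nei_li_distance(x2, r = 12)$D,
               nei_li_distance(x2, r = 6)$D / 2)
})

test_that("neighbour joining is exact on additive matrices", {
  # 3 taxa: unique star resolution in closed form
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(tree_distances(t3), D3, tolerance = 1e-12)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))

  # equidistant 4 taxa: zero-length internal branch
  D4 <- matrix(1, 4, 4) - diag(4)
  dimnames(D4) <- list(letters[1:4], letters[1:4])
  t4 <- neighbor_joining(D4)
  internal <- t4$edge[, 2] > length(t4$tip.label)
  expect_equal(unname(t4$edge.length[internal]), 0)

  # random additive 4- and 5-taxon matrices: topology via the four-point
  # oracle (n=4) / the generating tree (n=5), lengths via path distances
  for (s in 1:40) {
    ra <- random_additive(4, seed = 100 + s)
    tr <- neighbor_joining(ra$D)
    expect_equal(canonical_quartet_split(tr), four_point_split(ra$D))
    expect_equal(tree_distances(tr), ra$D, tolerance = 1e-9)
    rb <- random_additive(5, seed = 200 + s)
    tb <- neighbor_joining(rb$D)
    expect_setequal(bipartitions(tb), bipartitions(rb$tree))
    expect_equal(tree_distances(tb), rb$D, tolerance = 1e-9)
  }

  # independent implementation agrees on a non-additive matrix
  set.seed(77)
  M <- matrix(runif(64, 0.2, 1), 8, 8); M <- (M + t(M)) / 2; diag(M) <- 0
  dimnames(M) <- list(letters[1:8], letters[1:8])
  expect_setequal(bipartitions(neighbor_joining(M)),
                  bipartitions(ape::nj(M)))

  expect_error(neighbor_joining(matrix(0, 2, 2)), "three")
  Mna <- M; Mna[1, 2] <- Mna[2, 1] <- NA
  expect_error(neighbor_joining(Mna), "saturated")
})

test_that("negative NJ branch estimates are clamped with raw values kept", {
  # triangle-inequality violation forces a negative estimate for taxon c
  D <- matrix(c(0, 4, 1,
                4, 0, 1,
                1, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  raw <- attr(tr, "raw_edge_lengths")
  expect_true(any(raw < 0))
  expect_true(all(tr$edge.length >= 0))
  expect_equal(tr$edge.length[raw >= 0], raw[raw >= 0])
})

test_that("bootstrap supports are 100 on a congruent panel and absent at B=0", {
  x <- congruent_panel(30L)
  tr <- bootstrap_support(x, B = 50L, seed = 3L)
  sup <- tr$node.label[nzchar(tr$node.label)]
  expect_true(length(sup) >= 2)
  expect_true(all(sup == "100"))
  expect_equal(attr(tr, "effective_B"), 50L)
  t0 <- bootstrap_support(x, B = 0L)
  expect_null(t0$node.label)
  # supports from different seeds stay within binomial fluctuation
  sim <- simulate_diversity_panel(panel_sim_config(
    n_accessions = 10L, n_markers = 120L, k_subpop = 2L, divergence = 0.4,
    missing_rate = 0, seed = 6L))
  s1 <- bootstrap_support(sim$matrix, B = 200L, seed = 1L)
  s2 <- bootstrap_support(sim$matrix, B = 200L, seed = 2L)
  v1 <- suppressWarnings(as.numeric(s1$node.label)) / 100
  v2 <- suppressWarnings(as.numeric(s2$node.label)) / 100
  both <- !is.na(v1) & !is.na(v2)
  # 4 sd of the difference of two independent proportions at B = 200
  expect_true(all(abs(v1[both] - v2[both]) <= 0.2))
  # identical seeds give identical supports (determinism)
  expect_identical(bootstrap_support(sim$matrix, B = 50L, seed = 9L)$node.label,
                   bootstrap_support(sim$matrix, B = 50L, seed = 9L)$node.label)
})

test_that("PCoA recovers planted Euclidean configurations", {
  # collinear points: one positive axis carrying 100% of the variance
  pts <- cbind(c(0, 1, 3, 7), c(0, 2, 6, 14))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  res <- pcoa(D)
  expect_equal(ncol(res$coordinates), 1L)
  expect_equal(res$percent_variance[1], 100)

  # planted 2-D configuration recovered up to rotation/reflection
  set.seed(12)
  X <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(X))
  rownames(D2) <- colnames(D2) <- paste0("q", 1:10)
  r2 <- pcoa(D2)
  expect_equal(ncol(r2$coordinates), 2L)
  expect_lt(procrustes_error(X, r2$coordinates), 1e-9)
  expect_true(all(r2$percent_variance >= 0))
  expect_lte(sum(r2$percent_variance), 100 + 1e-9)

  # duplicated accession lands on identical coordinates
  X3 <- rbind(X, X[1, ])
  D3 <- as.matrix(dist(X3))
  rownames(D3) <- colnames(D3) <- paste0("r", 1:11)
  r3 <- pcoa(D3)
  expect_equal(unname(r3$coordinates[11, ]), unname(r3$coordinates[1, ]),
               tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("delta-K finds the planted knee and degenerates sanely", {
  hits <- 0L
  for (s in 1:25) {
    runs <- simulate_loglik_curves(true_k = 2, k_range = 1:10,
                                   replicates = 20L, noise_sd = 5, seed = s)
    hits <- hits + (delta_k(runs)$best_k == 2L)
  }
  expect_gte(hits, 24L)

  # linear mean curve: second difference is pure noise, delta-K small
  set.seed(3)
  lin <- data.frame(k = rep(1:8, each = 10),
                    loglik = rep(1:8 * 100, each = 10) + rnorm(80, 0, 5))
  dk <- delta_k(lin)$table$delta_k
  expect_true(all(dk < 3, na.rm = TRUE))
  expect_error(delta_k(data.frame(k = rep(1:2, each = 3),
                                  loglik = rnorm(6))), "3 consecutive")
  expect_error(delta_k(data.frame(k = c(1, 1, 2, 3, 3),
                                  loglik = rnorm(5))), ">= 2 replicates")
})
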