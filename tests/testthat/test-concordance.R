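test_that("detection uses a strict threshold and skips control probes", {
  af3 <- matrix(c(301, 300, 299, 5000), 4, 2)
  ns <- manual_ns(af3, is_control = c(FALSE, FALSE, FALSE, TRUE))
  d <- call_detection(ns, "g", threshold = 300)
  expect_length(d$detected, 3)                  # control probe excluded
  expect_identical(unname(d$detected), c(TRUE, FALSE, FALSE))
  d0 <- call_detection(ns, "g", threshold = 0)
  expect_true(all(d0$detected))
  expect_error(call_detection(ns, "nope"), "no usable arrays")
})

test_that("sensitivity/specificity follow the hand-count definitions", {
  mk <- function(detected) {
    structure(list(group = "t", mean_signal = NULL,
                   detected = setNames(detected, LETTERS[1:6]),
                   threshold = 300, n_arrays = 1), class = "DetectionProfile")
  }
  gold <- mk(c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = FALSE, F = FALSE))
  test <- mk(c(A = TRUE, B = TRUE, C = TRUE, D = FALSE, E = TRUE, F = FALSE))
  r <- sensitivity_specificity(test, gold)
  expect_equal(r$sensitivity, 3 / 4)
  expect_equal(r$specificity, 1 / 2)
  expect_equal(sum(r$counts), 6)               # counts sum to the universe
  # swapping test and gold: new sensitivity = old both/(both+test_only),
  # i.e. the positive-predictive analog of the same counts
  r2 <- sensitivity_specificity(gold, test)
  expect_equal(r2$sensitivity,
               r$counts[["both"]] / (r$counts[["both"]] + r$counts[["test_only"]]))
  expect_identical(sort(unname(r2$counts)), sort(unname(r$counts)))
})

test_that("credible intervals are Beta(s+1, f+1) equal-tailed quantiles", {
  ci <- scarray:::.beta_ci
  # s = f = 0: uniform posterior
  expect_equal(unname(ci(0, 0)), c(0.025, 0.975), tolerance = 1e-9)
  # s = 10, f = 0: Beta(11, 1), closed-form quantile q^(1/11)
  expect_equal(unname(ci(10, 0)), c(0.025^(1 / 11), 0.975^(1 / 11)),
               tolerance = 1e-9)
  # s = 7, f = 3: oracle by uniroot on the integrated Beta(8, 4) density
  dens <- function(t) t^7 * (1 - t)^3 / beta(8, 4)
  orc <- function(p) uniroot(function(q) integrate(dens, 0, q)$value - p,
                             c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  expect_equal(unname(ci(7, 3)), c(orc(0.025), orc(0.975)), tolerance = 1e-9)
})

test_that("M-ratio profiles restrict to probes detected in all groups", {
  af3 <- matrix(c(1000, 1000, 100,
                  1000, 1000, 100,
                  1000, 100, 1000,
                  1000, 100, 1000), 4, 3, byrow = FALSE)
  # columns: groups a, a, b (two arrays in a, one in b)
  af3 <- cbind(a1 = c(1000, 1000, 400, 100), a2 = c(1200, 900, 500, 120),
               b1 = c(800, 100, 600, 900))
  ns <- manual_ns(af3, groups = c("a", "a", "b"))
  da <- call_detection(ns, "a"); db <- call_detection(ns, "b")
  prof <- m_ratio_profile(ns, list(da, db))
  expect_identical(rownames(prof), c("P001", "P003"))  # detected in both
  expect_equal(prof["P001", "a"],
               mean(log2(af3[1, 1:2] / 100)))
})

test_that("M-ratio correlations satisfy affine invariance and a rank oracle", {
  x <- c(0.3, -1.2, 2.5, 0.8, -0.1)
  p <- cbind(a = x, b = x)
  expect_equal(m_ratio_correlations(p, "pearson"), 1.0)
  expect_equal(m_ratio_correlations(p, "spearman"), 1.0)
  p2 <- cbind(a = x, b = 2 * x + 3)
  expect_equal(m_ratio_correlations(p2, "pearson"), 1.0)
  # adjacent-rank transposition on 5 values: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  y <- x; o <- order(x); y[o[1]] <- x[o[2]]; y[o[2]] <- x[o[1]]
  rho_oracle <- 1 - 6 * (1 + 1) / (5 * (25 - 1))
  expect_equal(m_ratio_correlations(cbind(x, y), "spearman"), rho_oracle)
  expect_error(m_ratio_correlations(cbind(x[1:2], y[1:2])), "3 shared")
})

test_that("random-pair difference correlation is exact, seeded and shift-invariant", {
  set.seed(3)
  x <- rnorm(6); y <- 0.6 * x + rnorm(6, 0, 0.4)
  prof <- cbind(a = x, b = y)
  # exhaustive oracle over all 15 pairs
  ds <- t(combn(6, 2))
  oracle <- cor(x[ds[, 1]] - x[ds[, 2]], y[ds[, 1]] - y[ds[, 2]])
  r <- random_pair_difference_correlation(prof, n_pairs = 15, seed = 99)
  expect_equal(r$coefficient, oracle)
  expect_equal(nrow(unique(r$pairs)), 15)

  # identical and shifted profiles give exactly 1
  expect_equal(random_pair_difference_correlation(cbind(x, x), 15, 1)$coefficient, 1.0)
  expect_equal(random_pair_difference_correlation(cbind(x, x + 5), 15, 1)$coefficient, 1.0)

  # seeded reproducibility and pair-count bound
  r2 <- random_pair_difference_correlation(prof, n_pairs = 10, seed = 7)
  r3 <- random_pair_difference_correlation(prof, n_pairs = 10, seed = 7)
  expect_identical(r2, r3)
  expect_error(random_pair_difference_correlation(prof, n_pairs = 16, seed = 1),
               "exceeds")
})

test_that("pair-index decoding enumerates every unordered pair once", {
  for (n in c(4, 7, 30)) {
    ij <- scarray:::.decode_pairs(seq_len(choose(n, 2)), n)
    expect_true(all(ij[, 1] < ij[, 2]))
    expect_true(all(ij[, 2] <= n))
    expect_equal(nrow(unique(ij)), choose(n, 2))
  }
})

test_that("pairwise outlier scan flags an aberrant array", {
  set.seed(12)
  base <- rnorm(300)
  M <- sapply(1:6, function(i) base + rnorm(300, 0, 0.3))
  M[, 6] <- rnorm(300)                    # unrelated array
  af3 <- 2^(M + 10); af5 <- matrix(2^10, 300, 6)
  ns <- manual_ns(af3, af5, groups = rep("g", 6))
  rep <- pairwise_outlier_scan(ns, "g")
  expect_true(rep$exclusions$excluded[rep$exclusions$sample_id == "s06"])

  # identical arrays: all correlations 1, zero range, no outlier
  ns2 <- manual_ns(matrix(rep(2^(base + 10), 3), ncol = 3),
                   matrix(2^10, 300, 3), groups = rep("g", 3))
  rep2 <- pairwise_outlier_scan(ns2, "g")
  expect_equal(sum(rep2$exclusions$excluded), 0)

  ns3 <- manual_ns(af3[, 1:2], af5[, 1:2], groups = rep("g", 2))
  expect_error(pairwise_outlier_scan(ns3, "g"), "fewer than 3")
})

test_that("top-variable clustering separates distinct profiles", {
  set.seed(13)
  profA <- rnorm(500, 10, 2); profB <- rnorm(500, 10, 2)
  arrays <- cbind(sapply(1:4, function(i) profA + rnorm(500, 0, 0.2)),
                  sapply(1:4, function(i) profB + rnorm(500, 0, 0.2)))
  colnames(arrays) <- c(paste0("A", 1:4), paste0("B", 1:4))
  ns <- manual_ns(2^arrays, matrix(2^10, 500, 8),
                  groups = rep(c("pA", "pB"), each = 4))
  cl <- cluster_top_variable(ns, n_genes = 200)
  k2 <- cutree(cl$hclust, 2)
  expect_equal(length(unique(k2[paste0("A", 1:4)])), 1)
  expect_equal(length(unique(k2[paste0("B", 1:4)])), 1)
  expect_false(k2[["A1"]] == k2[["B1"]])

  # n_genes beyond the probe count uses all probes without error
  cl2 <- cluster_top_variable(ns, n_genes = 10000)
  expect_length(cl2$genes, 500)

  # duplicated arrays sit at zero distance and adjacent leaves
  ns3 <- manual_ns(2^arrays[, c(1, 1, 5)], matrix(2^10, 500, 3),
                   groups = c("x", "x", "y"))
  cl3 <- cluster_top_variable(ns3, n_genes = 100)
  ord <- cl3$leaf_order
  expect_equal(abs(diff(which(ord %in% c(1, 2)))), 1)
})

test_that("rank percentiles match brute-force ranking", {
  af3 <- matrix(c(10, 20, 30, 40, 50), 5, 2)
  ns <- manual_ns(af3, gene_symbol = c("g1", "g2", "g3", "g4", "g5"),
                  groups = c("a", "a"))
  rp <- rank_percentile(ns, c("g5", "g3"), digits = 2)
  expect_equal(rp["g5", "a"], 100)
  expect_equal(rp["g3", "a"], 3 / 5 * 100)
  # a gene with several probes takes the best probe
  ns2 <- manual_ns(af3, gene_symbol = c("g1", "g1", "g2", "g2", "g3"),
                  groups = c("a", "a"))
  rp2 <- rank_percentile(ns2, "g1", digits = 2)
  expect_equal(rp2["g1", "a"], 2 / 5 * 100)
  expect_error(rank_percentile(ns, "nope"), "none of the gene symbols")
})
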