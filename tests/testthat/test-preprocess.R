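make_day_es <- function(vals3, vals5, days, group = "1") {
  n <- length(days)
  ann <- data.frame(probe_id = sprintf("p%d", 1:4))
  meta <- data.frame(sample_id = sprintf("s%d", 1:n), group = group,
                     day = days, replicate = 1:n)
  experiment_set(ann, meta, matrix(vals3, 4, n, byrow = TRUE),
                 matrix(vals5, 4, n, byrow = TRUE))
}

test_that("day-effect correction equalizes day means and leaves one-day groups alone", {
  es <- make_day_es(c(100, 100, 120, 120), c(200, 200, 230, 230),
                    days = c("1", "1", "2", "2"))
  out <- day_effect_correct(es)
  expect_equal(unname(attr(out, "day_shifts")[["1"]]), c(20, 30))
  expect_equal(out$af3[, 3:4], es$af3[, 3:4] - 20)
  expect_equal(out$af3[, 1:2], es$af3[, 1:2])          # day 1 untouched
  expect_equal(mean(out$af3[, 1:2]), mean(out$af3[, 3:4]))
  expect_equal(mean(out$af5[, 1:2]), mean(out$af5[, 3:4]))

  one_day <- make_day_es(c(100, 100, 120, 120), c(200, 200, 230, 230),
                         days = rep("1", 4))
  expect_identical(day_effect_correct(one_day)$af3, one_day$af3)

  three <- make_day_es(rep(1, 3), rep(1, 3), days = c("1", "2", "3"))
  expect_error(day_effect_correct(three), "2-day")
})

test_that("injected day shift is recovered from synthetic data", {
  cfg <- sim_config(n_probes = 8000,
                    groups = data.frame(cell_count = 5L, n_replicates = 10L),
                    day_shift_af3 = 40, day_shift_af5 = 25,
                    noise_logsd = 0.05, abundance_logmean = log(3),
                    abundance_logsd = 0.3, capture_prob = 1, seed = 21)
  es <- simulate_experiment(cfg)
  out <- day_effect_correct(es)
  sh <- attr(out, "day_shifts")[["5"]]
  # estimate = injected shift + replicate sampling noise of group means
  expect_lt(abs(sh[["af3"]] - 40), 15)
  expect_lt(abs(sh[["af5"]] - 25), 15)
  # post-correction day means agree exactly within the group
  d1 <- es$samples$day == "1"
  expect_equal(mean(out$af3[, d1]), mean(out$af3[, !d1]))
})

test_that("normexp correction matches a numerical-integration conditional mean", {
  mu <- 100; sigma <- 10; alpha <- 1000
  # oracle: E[S | X = x] by direct numerical integration of the
  # normal-background + exponential-signal convolution
  oracle <- function(x) {
    f <- function(s) dexp(s, 1 / alpha) * dnorm(x - s, mu, sigma)
    # the posterior concentrates near max(0, x - mu) with width ~ sigma
    lo <- max(0, x - mu - 12 * sigma)
    hi <- max(0, x - mu) + 12 * sigma
    num <- integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-10)$value
    den <- integrate(f, lo, hi, rel.tol = 1e-10)$value
    num / den
  }
  xs <- c(80, 100, 150, 300, 1000, 5000)
  closed <- scarray:::.normexp_signal(xs, mu, sigma, alpha)
  expect_equal(closed, vapply(xs, oracle, 0), tolerance = 1e-6)

  # full path with estimated parameters on simulated data
  set.seed(77)
  x <- rnorm(5000, mu, sigma) + rexp(5000, 1 / alpha)
  corrected <- normexp_correct(x, offset = 50)
  expected <- vapply(x[1:500], oracle, 0) + 50
  rms <- sqrt(mean((corrected[1:500] - expected)^2))
  expect_lt(rms / alpha, 0.05)   # estimation error well under 5% of the signal scale
})

test_that("normexp output is positive, rank-preserving, with the x - mu + offset asymptote", {
  set.seed(78)
  x <- rnorm(2000, 100, 10) + rexp(2000, 1 / 1000)
  out <- normexp_correct(x, offset = 50)
  expect_true(all(out > 0))
  expect_identical(order(out), order(x))            # monotone
  big <- which.max(x)
  expect_lt(abs(out[big] - (x[big] - 100 + 50)), 25)

  expect_warning(res <- normexp_correct(rep(7, 20)), "degenerate")
  expect_equal(res, rep(50, 20))
})

test_that("loess normalization removes the M-on-A trend", {
  set.seed(5)
  A <- runif(500, 4, 14)
  expect_equal(loess_normalize(rep(0, 500), A), rep(0, 500))
  expect_equal(loess_normalize(rep(2, 500), A), rep(0, 500), tolerance = 1e-9)
  M <- 0.5 * A + rnorm(500, 0, 0.01)
  resid <- loess_normalize(M, A)
  slope <- coef(lm(resid ~ A))[["A"]]
  expect_lt(abs(slope), 0.02)
  expect_error(loess_normalize(1:5, 1:5), "10 points")
})

test_that("quantile normalization matches the order-statistic-mean definition", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m, on_log_scale = TRUE)
  expect_equal(unname(out), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  m2 <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantile_normalize(m2, on_log_scale = TRUE), m2)

  # column-permutation equivariance
  set.seed(6)
  m3 <- matrix(runif(40, 1, 100), 10, 4, dimnames = list(NULL, letters[1:4]))
  out3 <- quantile_normalize(m3)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(quantile_normalize(m3[, perm])), unname(out3[, perm]))

  expect_warning(out1 <- quantile_normalize(m3[, 1, drop = FALSE]), "single array")
  expect_equal(out1, m3[, 1, drop = FALSE])
})

test_that("quantile normalization agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  lm2 <- matrix(rnorm(200, 10, 2), 50, 4)
  ours <- quantile_normalize(lm2, on_log_scale = TRUE)
  ref <- limma::normalizeQuantiles(lm2)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("run_preprocess applies four recorded steps deterministically", {
  es <- simulate_experiment(tiny_config(seed = 9))
  ns1 <- run_preprocess(es)
  ns2 <- run_preprocess(es)
  expect_identical(ns1$af3, ns2$af3)
  expect_identical(ns1$M, ns2$M)
  expect_equal(vapply(ns1$provenance, `[[`, "", "step"),
               c("day_effect_correct", "normexp_correct",
                 "loess_normalize", "quantile_normalize"))
  # after quantile normalization, sorted per-array log2 vectors agree
  for (g in unique(ns1$samples$group)) {
    cols <- which(ns1$samples$group == g)
    sorted <- apply(log2(ns1$af3[, cols]), 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  }
  # M and A are consistent with the final matrices
  expect_equal(ns1$M, log2(ns1$af3) - log2(ns1$af5))
})

test_that("qc-excluded samples are dropped before normalization", {
  es <- simulate_experiment(tiny_config(seed = 10))
  es$samples$qc_excluded[1] <- TRUE
  es$samples$qc_reason[1] <- "yield"
  ns <- run_preprocess(es)
  expect_false(es$samples$sample_id[1] %in% ns$samples$sample_id)
})
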