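# independent step-by-step running-sum oracle used against enrichment_score
es_oracle <- function(scores, hits, p) {
  N <- length(scores); nh <- sum(hits)
  run <- numeric(N); cur <- 0
  sw <- sum(abs(scores[hits])^p)
  for (i in seq_len(N)) {
    cur <- if (hits[i]) cur + abs(scores[i])^p / sw else cur - 1 / (N - nh)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

mk_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  ord <- order(-scores, genes)
  structure(data.frame(gene = genes[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedList", "data.frame"))
}

test_that("ranked lists are mean-centered, collapsed by max, deterministically ordered", {
  af3 <- 2^matrix(c(10, 8, 6, 4), 4, 2)
  ns <- manual_ns(af3, gene_symbol = c("gA", "gA", "gB", "gC"),
                  groups = c("x", "x"))
  rl <- build_ranked_list(ns, "x")
  expect_equal(sum(rl$score), 0)
  expect_identical(rl$gene, c("gA", "gB", "gC"))       # gA collapsed to max (10)
  expect_equal(rl$score, c(10, 6, 4) - mean(c(10, 6, 4)))

  # single gene
  ns1 <- manual_ns(af3[1, , drop = FALSE], gene_symbol = "solo",
                   groups = c("x", "x"))
  rl1 <- build_ranked_list(ns1, "x")
  expect_identical(rl1$gene, "solo")

  # tie-breaking is lexicographic, hence reproducible
  af3t <- 2^matrix(c(5, 5, 5), 3, 1)
  nst <- manual_ns(af3t, gene_symbol = c("zz", "aa", "mm"), groups = "x")
  expect_identical(build_ranked_list(nst, "x")$gene, c("aa", "mm", "zz"))
})

test_that("enrichment score equals the brute-force running sum", {
  # p = 0, 4 genes, set = top 2: running sum peaks at 1
  rl <- mk_ranked(c(4, 3, 2, 1))
  r <- enrichment_score(rl, c("g01", "g02"), p = 0)
  expect_equal(r$es, 1.0)

  # set covering the whole list: ES = +1 by convention
  expect_equal(enrichment_score(rl, sprintf("g%02d", 1:4))$es, 1.0)

  # 10-gene list, 3-member set, p in {0, 1}: independent oracle
  set.seed(21)
  scores <- sort(rnorm(10), decreasing = TRUE)
  rl10 <- mk_ranked(scores)
  members <- rl10$gene[c(2, 5, 9)]
  hits <- rl10$gene %in% members
  for (p in c(0, 1)) {
    expect_equal(enrichment_score(rl10, members, p = p)$es,
                 es_oracle(rl10$score, hits, p))
  }
  expect_error(enrichment_score(rl10, c("absent")), "no member")
})

test_that("ES stays in [-1, 1] and is shift-invariant at p = 0", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    rl <- mk_ranked(rnorm(n))
    members <- sample(rl$gene, sample(1:(n - 1), 1))
    es <- enrichment_score(rl, members, p = 1)$es
    expect_gte(es, -1); expect_lte(es, 1)
    es0 <- enrichment_score(rl, members, p = 0)$es
    rl_shift <- rl; rl_shift$score <- rl$score + 7
    expect_equal(enrichment_score(rl_shift, members, p = 0)$es, es0)
  }
})

test_that("permutation NES/FDR is seeded and finds a planted set", {
  set.seed(23)
  scores <- sort(rnorm(120, 0, 1), decreasing = TRUE)
  rl <- mk_ranked(scores, sprintf("g%03d", 1:120))
  planted <- list(name = "planted", description = "",
                  members = rl$gene[1:12])          # occupies the top
  rand_sets <- lapply(1:4, function(i)
    list(name = paste0("rand", i), description = "",
         members = sample(rl$gene, 12)))
  sets <- c(list(planted = planted), setNames(rand_sets, paste0("rand", 1:4)))
  res <- nes_and_fdr(rl, sets, n_perm = 500, seed = 31)
  expect_lt(res$q_value[res$name == "planted"], 0.05)
  expect_equal(sign(res$nes), sign(res$es))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))

  res2 <- nes_and_fdr(rl, sets, n_perm = 500, seed = 31)
  expect_identical(res, res2)
})

test_that("nominal p of random sets is roughly uniform", {
  set.seed(24)
  scores <- sort(rnorm(80), decreasing = TRUE)
  rl <- mk_ranked(scores, sprintf("g%03d", 1:80))
  ps <- vapply(1:30, function(i) {
    s <- list(name = "s", description = "", members = sample(rl$gene, 10))
    nes_and_fdr(rl, list(s = s), n_perm = 100, seed = 100 + i)$p_value
  }, 0)
  expect_gt(mean(ps), 0.25)      # not systematically significant
  expect_lt(mean(ps), 0.75)      # not systematically inflated
})

test_that("NES correlation behaves on matched collections", {
  a <- structure(data.frame(name = c("s1", "s2", "s3", "s4"),
                            nes = c(2, -1, 0.5, 1.2)),
                 class = c("GseaResult", "data.frame"))
  b <- a; expect_equal(correlate_nes(a, b), 1.0)
  b$nes <- -a$nes; expect_equal(correlate_nes(a, b), -1.0)
  expect_error(correlate_nes(a, a[1:2, ]), "3 shared")
})
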