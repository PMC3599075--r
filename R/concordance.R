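# Detection calling and concordance statistics between cell-number groups:
# sensitivity/specificity with Beta posterior credible intervals, M-ratio
# correlations, the seeded random-pair difference-of-M-ratio statistic,
# a pairwise-correlation outlier scan, clustering of the most variable
# genes, and rank percentiles of selected genes.

#' Call detected probes in one group
#'
#' A probe is detected when its across-array mean normalized
#' sample-channel signal strictly exceeds the threshold (default 300,
#' linear scale).  Control probes are excluded from the universe;
#' QC-excluded arrays do not contribute to the average.
#'
#' @param ns NormalizedSet from [run_preprocess()].
#' @param group group label.
#' @param threshold detection threshold in signal units.
#' @return a `DetectionProfile`: list with `group`, `mean_signal` (named,
#'   non-control probes), `detected` (logical, same names), `threshold`,
#'   `n_arrays`.
#' @export
call_detection <- function(ns, group, threshold = 300) {
  in_g <- ns$samples$group == group & !ns$samples$qc_excluded
  if (!any(in_g)) stop(sprintf("no usable arrays in group '%s'", group),
                       call. = FALSE)
  keep <- !ns$annotation$is_control
  m <- rowMeans(ns$af3[keep, in_g, drop = FALSE])
  structure(list(group = group, mean_signal = m, detected = m > threshold,
                 threshold = threshold, n_arrays = sum(in_g)),
            class = "DetectionProfile")
}

#' @export
print.DetectionProfile <- function(x, ...) {
  cat(sprintf("DetectionProfile '%s': %d / %d probes detected (threshold %g, %d arrays)\n",
              x$group, sum(x$detected), length(x$detected), x$threshold,
              x$n_arrays))
  invisible(x)
}

# equal-tailed credible interval of a proportion: Beta(s + 1, f + 1)
# posterior under a uniform prior
.beta_ci <- function(s, f, level = 0.95) {
  a <- (1 - level) / 2
  c(lower = stats::qbeta(a, s + 1, f + 1),
    upper = stats::qbeta(1 - a, s + 1, f + 1))
}

#' Detection sensitivity and specificity against a gold standard
#'
#' Sensitivity is the proportion of the gold standard's detected probes
#' that the test profile also detects; specificity is the proportion of
#' the gold standard's undetected probes that the test profile also fails
#' to detect.  Credible intervals are equal-tailed quantiles of the
#' Beta(s + 1, f + 1) posterior under a uniform prior, where s counts
#' concordant and f discordant probes.
#'
#' @param test,gold `DetectionProfile`s over the same probe universe.
#' @param level credible level (default 0.95).
#' @return a `ConcordanceReport` list: `counts` (both, gold_only,
#'   test_only, neither), `sensitivity`, `specificity`, their CIs, and the
#'   group labels.
#' @export
sensitivity_specificity <- function(test, gold, level = 0.95) {
  stopifnot(inherits(test, "DetectionProfile"), inherits(gold, "DetectionProfile"))
  if (!identical(names(test$detected), names(gold$detected)))
    stop("test and gold profiles cover different probe universes", call. = FALSE)
  td <- test$detected; gd <- gold$detected
  counts <- c(both = sum(td & gd), gold_only = sum(!td & gd),
              test_only = sum(td & !gd), neither = sum(!td & !gd))
  sens <- counts[["both"]] / (counts[["both"]] + counts[["gold_only"]])
  spec <- counts[["neither"]] / (counts[["neither"]] + counts[["test_only"]])
  structure(list(test_group = test$group, gold_group = gold$group,
                 counts = counts, universe = length(td),
                 sensitivity = sens,
                 sensitivity_ci = .beta_ci(counts[["both"]],
                                           counts[["gold_only"]], level),
                 specificity = spec,
                 specificity_ci = .beta_ci(counts[["neither"]],
                                           counts[["test_only"]], level),
                 level = level),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("Concordance %s vs gold %s (universe %d probes)\n",
              x$test_group, x$gold_group, x$universe))
  cat(sprintf("  sensitivity %.3f [%.3f, %.3f]  specificity %.3f [%.3f, %.3f]\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  if (!is.null(x$pearson))
    cat(sprintf("  M-ratio Pearson %.3f, Spearman %.3f, random-pair diff %.3f (%d pairs)\n",
                x$pearson, x$spearman, x$pair_diff_pearson, x$n_pairs))
  invisible(x)
}

#' Mean M-ratio profiles restricted to commonly detected probes
#'
#' Per-probe mean M (log2 sample/reference) per group, restricted to the
#' probes detected in every requested group — relative signal comparisons
#' are only meaningful where all profiles register signal.
#'
#' @param ns NormalizedSet.
#' @param detections list of `DetectionProfile`s (one per group compared).
#' @return probe x group matrix of mean M values, class `MRatioProfile`.
#' @export
m_ratio_profile <- function(ns, detections) {
  stopifnot(length(detections) >= 1)
  det <- Reduce(`&`, lapply(detections, `[[`, "detected"))
  probes <- names(det)[det]
  groups <- vapply(detections, `[[`, "", "group")
  out <- vapply(groups, function(g) {
    in_g <- ns$samples$group == g & !ns$samples$qc_excluded
    rowMeans(ns$M[probes, in_g, drop = FALSE])
  }, numeric(length(probes)))
  out <- matrix(out, nrow = length(probes),
                dimnames = list(probes, groups))
  class(out) <- c("MRatioProfile", class(out))
  out
}

#' Correlation of M-ratio profiles between two groups
#'
#' @param profile `MRatioProfile` with >= 2 columns, or a 2-column matrix
#'   of paired per-probe mean M values.
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
m_ratio_correlations <- function(profile, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(ncol(profile) >= 2)
  if (nrow(profile) < 3)
    stop("m_ratio_correlations: need >= 3 shared probes", call. = FALSE)
  stats::cor(profile[, 1], profile[, 2], method = method)
}

# decode 1-based index m into an unordered pair (i, j), i < j, with pairs
# enumerated (1,2), (1,3), ..., (1,n), (2,3), ...
.decode_pairs <- function(m, n) {
  cum <- cumsum((n - 1):1)
  i <- findInterval(m - 1, cum) + 1L
  j <- i + (m - c(0, cum)[i])
  cbind(i = i, j = as.integer(j))
}

#' Correlation of random-pair M-ratio differences between two groups
#'
#' Samples `n_pairs` distinct unordered probe pairs uniformly without
#' replacement (seeded), forms the within-group difference
#' `D = M_i - M_j` for each pair, and returns the Pearson correlation of
#' the differences across the two groups — a measure of whether
#' gene-to-gene ratios are preserved.  With `n_pairs` equal to the total
#' number of pairs this reproduces the exhaustive statistic exactly.
#'
#' @param profile `MRatioProfile` (or 2-column matrix) over the probes
#'   detected in both groups.
#' @param n_pairs number of pairs, at most `choose(n, 2)`.
#' @param seed integer seed.
#' @return list with `coefficient`, `pairs` (data.frame of probe index
#'   pairs), `n_pairs`, `seed`.
#' @export
random_pair_difference_correlation <- function(profile, n_pairs = 10000,
                                               seed = 1L) {
  stopifnot(ncol(profile) >= 2)
  n <- nrow(profile)
  if (n < 2) stop("need >= 2 shared probes", call. = FALSE)
  total <- choose(n, 2)
  if (n_pairs > total)
    stop(sprintf("n_pairs (%d) exceeds the %d available pairs", n_pairs, total),
         call. = FALSE)
  set.seed(seed)
  idx <- sample.int(total, n_pairs)
  ij <- .decode_pairs(idx, n)
  d1 <- profile[ij[, 1], 1] - profile[ij[, 2], 1]
  d2 <- profile[ij[, 1], 2] - profile[ij[, 2], 2]
  list(coefficient = stats::cor(d1, d2),
       pairs = data.frame(i = ij[, 1], j = ij[, 2]),
       n_pairs = n_pairs, seed = seed)
}

#' Pairwise-correlation outlier scan within a group
#'
#' Computes all pairwise Pearson correlations of the per-array M vectors
#' of one group, averages each array's correlation with the others, and
#' applies Dixon's Q test to those means to flag an aberrant array.
#'
#' @param ns NormalizedSet.
#' @param group group label with >= 3 arrays.
#' @param alpha Dixon significance level.
#' @param seed Monte-Carlo null seed.
#' @return a `QCReport` (see [flag_outlier_samples()]) for the criterion
#'   `"m_pairwise_correlation"`, with the correlation matrix attached as
#'   attribute `cor_matrix`.
#' @export
pairwise_outlier_scan <- function(ns, group, alpha = 0.05, seed = 1L) {
  in_g <- ns$samples$group == group & !ns$samples$qc_excluded
  if (sum(in_g) < 3)
    stop(sprintf("pairwise_outlier_scan: group '%s' has fewer than 3 arrays", group),
         call. = FALSE)
  M <- ns$M[, in_g, drop = FALSE]
  cm <- stats::cor(M)
  mean_cor <- (rowSums(cm) - 1) / (ncol(cm) - 1)
  rep <- flag_outlier_samples(
    data.frame(sample_id = colnames(M), group = group,
               criterion = "m_pairwise_correlation", value = mean_cor,
               stringsAsFactors = FALSE),
    alpha = alpha, seed = seed)
  attr(rep, "cor_matrix") <- cm
  rep
}

#' Hierarchical clustering of the most variable genes
#'
#' Selects the top `n_genes` probes by variance of log2 sample-channel
#' signal across arrays and clusters the arrays hierarchically (default:
#' average linkage on 1 - Pearson correlation distance).
#'
#' @param ns NormalizedSet with >= 2 arrays.
#' @param n_genes number of most-variable probes to use (default 1000;
#'   capped at the number available).
#' @param linkage an [stats::hclust()] method.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @return a `ClusterResult`: `genes`, `hclust`, `leaf_order`, `labels`.
#' @export
cluster_top_variable <- function(ns, n_genes = 1000,
                                 linkage = "average",
                                 distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  keep <- !ns$samples$qc_excluded
  if (sum(keep) < 2) stop("cluster_top_variable: need >= 2 arrays", call. = FALSE)
  l2 <- log2(ns$af3[!ns$annotation$is_control, keep, drop = FALSE])
  v <- apply(l2, 1, stats::var)
  n_genes <- min(n_genes, nrow(l2))
  top <- names(sort(v, decreasing = TRUE))[seq_len(n_genes)]
  sub <- l2[top, , drop = FALSE]
  d <- if (distance == "pearson") stats::as.dist(1 - stats::cor(sub))
       else stats::dist(t(sub))
  hc <- stats::hclust(d, method = linkage)
  structure(list(genes = top, hclust = hc, leaf_order = hc$order,
                 labels = colnames(sub)[hc$order],
                 sample_groups = stats::setNames(ns$samples$group[keep],
                                                 ns$samples$sample_id[keep])),
            class = "ClusterResult")
}

#' Export a cluster tree as Newick
#' @param cl `ClusterResult`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cluster_newick <- function(cl, path) {
  ape::write.tree(ape::as.phylo(cl$hclust), file = path)
  invisible(path)
}

#' Rank percentile of selected genes per group
#'
#' The percentile of each gene's mean normalized sample-channel signal
#' within the full probe signal distribution of each group (genes mapping
#' to several probes take the maximum over their probes).
#'
#' @param ns NormalizedSet.
#' @param gene_symbols character vector of gene symbols.
#' @param groups group labels (default: all).
#' @param digits rounding of the reported percentile (default 0, matching
#'   whole-percentile reporting).
#' @return gene x group matrix of percentiles in (0, 100].
#' @export
rank_percentile <- function(ns, gene_symbols, groups = NULL, digits = 0) {
  if (is.null(groups)) groups <- unique(ns$samples$group)
  found <- gene_symbols %in% ns$annotation$gene_symbol
  if (!any(found)) stop("none of the gene symbols map to a probe", call. = FALSE)
  if (any(!found))
    warning("symbols with no probe: ", paste(gene_symbols[!found], collapse = ", "))
  gene_symbols <- gene_symbols[found]
  out <- matrix(NA_real_, length(gene_symbols), length(groups),
                dimnames = list(gene_symbols, groups))
  n <- nrow(ns$af3)
  for (g in groups) {
    in_g <- ns$samples$group == g & !ns$samples$qc_excluded
    m <- rowMeans(ns$af3[, in_g, drop = FALSE])
    pct <- rank(m, ties.method = "average") / n * 100
    for (sym in gene_symbols) {
      probes <- ns$annotation$probe_id[ns$annotation$gene_symbol == sym]
      out[sym, g] <- round(max(pct[probes]), digits)
    }
  }
  out
}
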